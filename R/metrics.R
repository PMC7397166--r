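#' Confusion counts for binary predictions
#'
#' Tallies true/false positives and negatives with 1 as the positive class.
#'
#' @param predicted,actual Binary (0/1) vectors of equal length.
#' @return A named integer vector with elements `tp`, `tn`, `fp`, `fn`.
#' @examples
#' confusion_counts(c(1, 0, 1, 1), c(1, 0, 0, 1))
#' @export
confusion_counts <- function(predicted, actual) {
  if (length(predicted) != length(actual)) {
    abort("`predicted` and `actual` must have the same length.")
  }
  if (length(predicted) == 0L) abort("empty prediction vector.")
  predicted <- as.integer(predicted)
  actual <- as.integer(actual)
  stopifnot_binary(predicted, "predicted")
  stopifnot_binary(actual, "actual")
  c(
    tp = sum(predicted == 1L & actual == 1L),
    tn = sum(predicted == 0L & actual == 0L),
    fp = sum(predicted == 1L & actual == 0L),
    fn = sum(predicted == 0L & actual == 1L)
  )
}

#' Matthews correlation coefficient
#'
#' MCC on a binary confusion matrix: +1 is perfect prediction, 0 is
#' no better than chance, -1 is total inversion. When any marginal of the
#' confusion matrix is empty the denominator vanishes and the value is
#' defined as 0 (the chance-level convention).
#'
#' @param counts Named vector as returned by [confusion_counts()], or a
#'   numeric vector of length 4 ordered (tp, tn, fp, fn).
#' @return A number in \[-1, 1\].
#' @examples
#' mcc(confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))) # 1
#' @export
mcc <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 4L || any(counts < 0) || sum(counts) == 0) {
    abort("`counts` must be 4 nonnegative counts (tp, tn, fp, fn) with a positive total.")
  }
  tp <- counts[1]; tn <- counts[2]; fp <- counts[3]; fn <- counts[4]
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' Classification accuracy from confusion counts
#'
#' @inheritParams mcc
#' @return A number in \[0, 1\].
#' @export
accuracy <- function(counts) {
  counts <- as.numeric(counts)
  (counts[1] + counts[2]) / sum(counts)
}

#' Efficiency index rho
#'
#' The model-ranking score rho = MCC x accuracy. The product acts as a
#' statistical conjunction of reliability (MCC) and accuracy, so a model must
#' be strong on both to rank highly; it penalises the overfitting signature
#' where accuracy climbs while MCC falls.
#'
#' @param mcc_value MCC in \[-1, 1\].
#' @param accuracy_value Accuracy in \[0, 1\].
#' @return The product, unclamped.
#' @examples
#' efficiency_index(0.97, 0.99)
#' @export
efficiency_index <- function(mcc_value, accuracy_value) {
  if (any(mcc_value < -1 | mcc_value > 1)) abort("`mcc_value` must lie in [-1, 1].")
  if (any(accuracy_value < 0 | accuracy_value > 1)) abort("`accuracy_value` must lie in [0, 1].")
  mcc_value * accuracy_value
}

#' Evaluate binary predictions
#'
#' One-row tibble with accuracy, MCC, the efficiency index rho, and the
#' confusion counts.
#'
#' @inheritParams confusion_counts
#' @return A tibble with columns `accuracy`, `mcc`, `rho`, `n_evaluated`,
#'   `tp`, `tn`, `fp`, `fn`.
#' @export
evaluate_predictions <- function(predicted, actual) {
  cts <- confusion_counts(predicted, actual)
  acc <- accuracy(cts)
  m <- mcc(cts)
  tibble(
    accuracy = acc, mcc = m, rho = efficiency_index(m, acc),
    n_evaluated = as.integer(sum(cts)),
    tp = cts[["tp"]], tn = cts[["tn"]], fp = cts[["fp"]], fn = cts[["fn"]]
  )
}

#' Epsilon threshold admitting a top fraction of candidates
#'
#' Chooses the fitness threshold epsilon so that at least the requested top
#' fraction of candidates pass the strict test rho > epsilon. With
#' `fraction = 0.33` this reproduces the "at least the top 33%" filtering
#' heuristic; ties at the boundary are all admitted, so the pass set can
#' exceed `ceiling(fraction * n)`.
#'
#' @param rhos Numeric vector of efficiency indices for eligible candidates
#'   (callers filter to MCC > 0 first).
#' @param fraction Fraction in (0, 1] of candidates to admit.
#' @return A list with `epsilon` (the largest representable value strictly
#'   below the smallest passing rho) and `pass` (indices into `rhos`).
#' @export
epsilon_for_fraction <- function(rhos, fraction = 0.33) {
  if (length(rhos) == 0L) abort("`rhos` must be nonempty.")
  if (fraction <= 0 || fraction > 1) abort("`fraction` must lie in (0, 1].")
  k <- ceiling(fraction * length(rhos))
  cutoff <- sort(rhos, decreasing = TRUE)[k]
  pass <- which(rhos >= cutoff)
  list(epsilon = min(rhos[pass]) - 2^-40, pass = pass)
}

#' Relative improvement percentage
#'
#' `100 * (final - baseline) / final`: how much of the final score was gained
#' over the baseline, on the final score's own scale.
#'
#' @param final Final (reference) value; must be nonzero for a defined result.
#' @param baseline Baseline value.
#' @return Percentage; `NA` where `final == 0` (undefined).
#' @examples
#' improvement_percentage(0.99, 0.75) # 24.24...
#' @export
improvement_percentage <- function(final, baseline) {
  out <- 100 * (final - baseline) / final
  out[final == 0] <- NA_real_
  out
}
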