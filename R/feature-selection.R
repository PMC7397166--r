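#' Equal-frequency discretization
#'
#' Bins a real-valued vector into `n_bins` equal-frequency bins on sorted
#' order. Equal values always share a bin (ties take the lowest rank), so
#' occupancies are balanced exactly when all values are distinct. A constant
#' vector collapses to bin 0.
#'
#' @param values Numeric vector with no missing values.
#' @param n_bins Number of bins (>= 2; clamped to the sample size with a
#'   warning when larger).
#' @param feature_id Optional source feature id carried in the result.
#' @return A `discretized_feature`: list with integer `bins` in
#'   `0..n_bins-1`, `n_bins`, and `feature_id`.
#' @export
discretize <- function(values, n_bins, feature_id = NA_character_) {
  if (anyNA(values)) abort("`values` must not contain missing values.")
  if (n_bins < 2L) abort("`n_bins` must be >= 2.")
  n <- length(values)
  if (n_bins > n) {
    warn(sprintf("n_bins (%d) exceeds sample count (%d); clamped.", n_bins, n))
    n_bins <- n
  }
  bins <- bin_codes(values, n_bins)
  structure(list(bins = bins, n_bins = as.integer(n_bins),
                 feature_id = feature_id),
            class = "discretized_feature")
}

# rank-then-bin: floor((rank - 1) * n_bins / n); min-ranks keep ties together
bin_codes <- function(values, n_bins) {
  r <- rank(values, ties.method = "min")
  as.integer(floor((r - 1) * n_bins / length(values)))
}

#' Plug-in mutual information of two discrete vectors
#'
#' The maximum-likelihood ("plug-in") estimate
#' `I = sum p(a,b) log(p(a,b) / (p(a) p(b)))` over observed cells, in nats.
#' Exactly zero for empirically independent tables; never negative.
#'
#' @param a,b Vectors of equal length interpreted as categorical codes.
#' @return Nonnegative mutual information in nats.
#' @examples
#' x <- rep(c(0, 1), 5)
#' mutual_information(x, x) # ln 2
#' @export
mutual_information <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have the same length.")
  if (length(a) == 0L) abort("empty input.")
  a <- as.integer(factor(a)) - 1L
  b <- as.integer(factor(b)) - 1L
  mi_codes(a, max(a) + 1L, b, max(b) + 1L)
}

# MI on pre-coded vectors: a in 0..(na-1), b in 0..(nb-1). Hot path.
mi_codes <- function(a, na, b, nb) {
  n <- length(a)
  pj <- tabulate(a * nb + b + 1L, nbins = na * nb) / n
  jm <- matrix(pj, nrow = nb)            # column a, row b
  pa <- .colSums(jm, nb, na)
  pb <- .rowSums(jm, nb, na)
  denom <- rep(pa, each = nb) * rep.int(pb, na)
  pos <- pj > 0
  max(0, sum(pj[pos] * log(pj[pos] / denom[pos])))
}

#' Greedy mutual-information feature selection
#'
#' Forward selection of `k` features against the binary label using one of
#' three information-theoretic criteria. All features are equal-frequency
#' discretized into `n_bins` bins first; joint variables are formed on the
#' product alphabet of two discretized features. Every method's first pick
#' maximizes the relevance I(X; Y); thereafter, with S the selected set:
#'
#' * `mrmr` maximizes `I(X;Y) - mean_s I(X;X_s)` (the difference form),
#' * `jmi` maximizes `sum_s I((X,X_s); Y)`,
#' * `jmim` maximizes `min_s I((X,X_s); Y)`.
#'
#' Ties break toward the lower feature index, so selection is fully
#' deterministic.
#'
#' @param data An [ito_dataset()] with no missing values.
#' @param method `"mrmr"`, `"jmi"` or `"jmim"`.
#' @param k Number of features to select (`1 <= k <= n_features`).
#' @param n_bins Discretization bins (default 5).
#' @return An `ito_selection`: tibble with columns `step`, `feature_id`,
#'   `score`, plus attributes `method` and `n_bins`.
#' @export
select_features <- function(data, method = c("mrmr", "jmi", "jmim"),
                            k, n_bins = 5) {
  stopifnot(inherits(data, "ito_dataset"))
  method <- match.arg(tolower(method), c("mrmr", "jmi", "jmim"))
  if (k <= 0) abort("`k` must be positive.")
  if (anyNA(data$matrix)) abort("data must be free of missing values.")
  nf <- n_features(data)
  if (k > nf) abort("`k` exceeds the number of features.")
  n <- n_samples(data)
  nb <- as.integer(min(n_bins, n))

  disc <- matrix(0L, nrow = n, ncol = nf)
  for (j in seq_len(nf)) disc[, j] <- bin_codes(data$matrix[, j], nb)
  y <- data$labels
  ny <- 2L

  rel <- vapply(seq_len(nf), function(j) mi_codes(disc[, j], nb, y, ny),
                numeric(1))

  selected <- integer(0)
  scores <- numeric(0)
  remaining <- seq_len(nf)
  # running criterion state per candidate
  red_sum <- numeric(nf)        # mRMR: sum of I(X; X_s)
  jmi_sum <- numeric(nf)        # JMI: sum of I((X,X_s); Y)
  jmim_min <- rep(Inf, nf)      # JMIM: min of I((X,X_s); Y)

  for (step in seq_len(k)) {
    if (step == 1L) {
      crit <- rel[remaining]
    } else {
      s <- selected[length(selected)]
      ds <- disc[, s]
      for (j in remaining) {
        if (method == "mrmr") {
          red_sum[j] <- red_sum[j] + mi_codes(disc[, j], nb, ds, nb)
        } else {
          jmi_js <- mi_codes(disc[, j] * nb + ds, nb * nb, y, ny)
          jmi_sum[j] <- jmi_sum[j] + jmi_js
          jmim_min[j] <- min(jmim_min[j], jmi_js)
        }
      }
      crit <- switch(method,
        mrmr = rel[remaining] - red_sum[remaining] / length(selected),
        jmi = jmi_sum[remaining],
        jmim = jmim_min[remaining]
      )
    }
    # ties (within numerical noise of the plug-in estimates) break toward
    # the lower feature index
    best_pos <- which(crit >= max(crit) - 1e-10)[1]
    pick <- remaining[best_pos]
    scores <- c(scores, crit[best_pos])
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }

  structure(
    tibble(step = seq_len(k), feature_id = data$feature_ids[selected],
           score = scores),
    method = method, n_bins = nb,
    class = c("ito_selection", class(tibble()))
  )
}
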