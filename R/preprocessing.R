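#' Drop features with missing values in the training set
#'
#' Features carrying any missing value in the *training* data are removed
#' from the training set and from every companion dataset: with features in
#' abundance, a probe that fails to cover the sample space is discarded
#' rather than imputed. Residual missing cells in companion datasets (within
#' surviving features) are imputed with the training median of the feature,
#' so downstream scaling and classification always see complete columns.
#'
#' @param train Training [ito_dataset()].
#' @param others List of companion datasets (e.g. the validation set) sharing
#'   `train`'s feature ids in the same order.
#' @return A list with `train`, `others`, `kept` (surviving feature ids) and
#'   `medians` (training medians of surviving features, used for imputation).
#' @export
exclude_missing_features <- function(train, others = list()) {
  stopifnot(inherits(train, "ito_dataset"))
  if (inherits(others, "ito_dataset")) others <- list(others)
  for (o in others) {
    if (!identical(o$feature_ids, train$feature_ids)) {
      abort("all datasets must share identical feature_ids in identical order.")
    }
  }
  keep <- !apply(is.na(train$matrix), 2, any)
  if (!any(keep)) abort("no features survive missing-value exclusion.")
  kept <- train$feature_ids[keep]
  tr_mat <- train$matrix[, keep, drop = FALSE]
  medians <- apply(tr_mat, 2, stats::median)
  train2 <- ito_dataset(tr_mat, train$labels, train$sample_ids, kept)
  others2 <- lapply(others, function(o) {
    m <- o$matrix[, keep, drop = FALSE]
    nas <- which(is.na(m), arr.ind = TRUE)
    if (nrow(nas) > 0L) m[nas] <- medians[nas[, 2]]
    ito_dataset(m, o$labels, o$sample_ids, kept)
  })
  list(train = train2, others = others2, kept = kept, medians = medians)
}

#' Fit a per-feature scaler on training data
#'
#' Supported methods: `"standard"` ((x - mean) / sd), `"robust"`
#' ((x - median) / IQR), `"quantile"` (empirical-CDF map of the training
#' values onto \[0, 1\] using (rank - 0.5) / n with averaged ranks for ties)
#' and `"none"` (identity). Constant features transform to 0 (0.5 under
#' quantile). Parameters are estimated from the training data only.
#'
#' @param train Training [ito_dataset()] with no missing values.
#' @param method Scaling method name.
#' @return A `fitted_scaler` bound to `train`'s feature ids.
#' @export
fit_scaler <- function(train, method = c("standard", "robust", "quantile", "none")) {
  stopifnot(inherits(train, "ito_dataset"))
  if (anyNA(train$matrix)) abort("apply exclude_missing_features() before scaling.")
  method <- match.arg(method)
  m <- train$matrix
  params <- switch(method,
    none = list(),
    standard = list(center = colMeans(m), scale = apply(m, 2, stats::sd)),
    robust = list(center = apply(m, 2, stats::median),
                  scale = apply(m, 2, stats::IQR)),
    quantile = list(knots = lapply(seq_len(ncol(m)), function(j) {
      v <- m[, j]
      # averaged ranks -> (rank - 0.5)/n, collapsed to unique value knots
      p <- (rank(v, ties.method = "average") - 0.5) / length(v)
      ord <- order(v)
      vu <- v[ord]; pu <- p[ord]
      dup <- duplicated(vu)
      list(x = vu[!dup], y = pu[!dup])
    }))
  )
  structure(list(method = method, params = params,
                 feature_ids = train$feature_ids),
            class = "fitted_scaler")
}

#' @export
print.fitted_scaler <- function(x, ...) {
  cat(sprintf("<fitted_scaler> method=%s, %d features\n",
              x$method, length(x$feature_ids)))
  invisible(x)
}

#' Apply a fitted scaler
#'
#' Transforms a dataset with parameters learnt on training data. Standard and
#' robust scaling extrapolate linearly by formula; the quantile map clips
#' values outside the training range to \[0, 1\] and interpolates linearly
#' between training-value knots inside it. Features with zero spread map to
#' 0 (0.5 under quantile).
#'
#' @param scaler A `fitted_scaler`.
#' @param data An [ito_dataset()] with exactly the scaler's feature ids.
#' @return The transformed [ito_dataset()].
#' @export
apply_scaler <- function(scaler, data) {
  stopifnot(inherits(scaler, "fitted_scaler"), inherits(data, "ito_dataset"))
  if (!identical(data$feature_ids, scaler$feature_ids)) {
    abort("dataset features do not match the scaler's bound feature_ids.")
  }
  m <- data$matrix
  out <- switch(scaler$method,
    none = m,
    standard = scale_linear(m, scaler$params$center, scaler$params$scale),
    robust = scale_linear(m, scaler$params$center, scaler$params$scale),
    quantile = {
      res <- m
      for (j in seq_len(ncol(m))) {
        kn <- scaler$params$knots[[j]]
        if (length(kn$x) == 1L) {
          res[, j] <- ifelse(m[, j] < kn$x, 0, ifelse(m[, j] > kn$x, 1, 0.5))
        } else {
          v <- stats::approx(kn$x, kn$y, xout = m[, j], rule = 2)$y
          v[m[, j] < kn$x[1]] <- 0
          v[m[, j] > kn$x[length(kn$x)]] <- 1
          res[, j] <- v
        }
      }
      res
    }
  )
  ito_dataset(out, data$labels, data$sample_ids, data$feature_ids)
}

scale_linear <- function(m, center, scale) {
  out <- sweep(m, 2, center, "-")
  zero <- scale <= 0
  scale[zero] <- 1
  out <- sweep(out, 2, scale, "/")
  if (any(zero)) out[, zero] <- 0
  out
}
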