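#' Expression dataset container
#'
#' Canonical in-memory representation of an expression dataset: a
#' samples-in-rows numeric matrix with binary class labels (1 = positive).
#' Missing intensities are represented by `NA`.
#'
#' @param matrix Numeric matrix, samples in rows.
#' @param labels Binary (0/1) vector, one per sample.
#' @param sample_ids,feature_ids Unique identifier character vectors; default
#'   to the matrix dimnames or generated ids.
#' @param require_both_classes If `TRUE` (the default for training data),
#'   demand at least one sample of each class.
#' @return An `ito_dataset` object.
#' @export
ito_dataset <- function(matrix, labels, sample_ids = rownames(matrix),
                        feature_ids = colnames(matrix),
                        require_both_classes = FALSE) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (is.null(sample_ids)) sample_ids <- sprintf("s%04d", seq_len(nrow(matrix)))
  if (is.null(feature_ids)) feature_ids <- sprintf("f%05d", seq_len(ncol(matrix)))
  labels <- as.integer(labels)
  if (nrow(matrix) != length(labels) || nrow(matrix) != length(sample_ids)) {
    abort("matrix rows, labels and sample_ids must agree in length.")
  }
  if (ncol(matrix) != length(feature_ids)) {
    abort("matrix columns and feature_ids must agree in length.")
  }
  stopifnot_binary(labels, "labels")
  if (anyDuplicated(sample_ids)) abort("duplicate sample_ids.")
  if (anyDuplicated(feature_ids)) abort("duplicate feature_ids.")
  if (require_both_classes && length(unique(labels)) < 2L) {
    abort("dataset must contain at least one sample of each class.")
  }
  dimnames(matrix) <- list(sample_ids, feature_ids)
  structure(
    list(matrix = matrix, labels = labels,
         sample_ids = as.character(sample_ids),
         feature_ids = as.character(feature_ids)),
    class = "ito_dataset"
  )
}

#' @export
print.ito_dataset <- function(x, ...) {
  cat(sprintf(
    "<ito_dataset> %d samples x %d features (%d positive, %d negative, %d missing cells)\n",
    n_samples(x), n_features(x), sum(x$labels == 1L), sum(x$labels == 0L),
    sum(is.na(x$matrix))
  ))
  invisible(x)
}

#' @export
dim.ito_dataset <- function(x) dim(x$matrix)

#' Sample and feature counts
#' @param x An `ito_dataset`.
#' @return An integer count.
#' @export
n_samples <- function(x) nrow(x$matrix)

#' @rdname n_samples
#' @export
n_features <- function(x) ncol(x$matrix)

#' @export
as_tibble.ito_dataset <- function(x, ...) {
  dplyr::bind_cols(
    tibble(.sample = x$sample_ids, .label = x$labels),
    as_tibble(as.data.frame(x$matrix), .name_repair = "minimal")
  )
}

# Subset features by id (order preserved as given).
select_dataset_features <- function(x, ids) {
  missing <- setdiff(ids, x$feature_ids)
  if (length(missing) > 0L) {
    abort(sprintf("features not present in dataset: %s",
                  paste(utils::head(missing, 5), collapse = ", ")))
  }
  ito_dataset(x$matrix[, ids, drop = FALSE], x$labels,
              sample_ids = x$sample_ids, feature_ids = ids)
}

#' Summarize an expression dataset
#'
#' @param dataset An `ito_dataset`.
#' @return A one-row tibble with sample, class, feature and missing-cell
#'   counts.
#' @export
summarize_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "ito_dataset"))
  tibble(
    n_samples = n_samples(dataset),
    n_features = n_features(dataset),
    n_positive = sum(dataset$labels == 1L),
    n_negative = sum(dataset$labels == 0L),
    n_missing = sum(is.na(dataset$matrix))
  )
}
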