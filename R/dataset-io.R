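MISSING_TOKENS <- c("", "na", "nan", "null")

parse_numeric_cells <- function(chr, where) {
  chr_trim <- trimws(chr)
  is_missing <- tolower(chr_trim) %in% MISSING_TOKENS | is.na(chr_trim)
  out <- suppressWarnings(as.numeric(chr_trim))
  bad <- !is_missing & is.na(out)
  if (any(bad)) {
    abort(sprintf("non-numeric cell(s) in %s: %s", where,
                  paste(utils::head(unique(chr_trim[bad]), 5), collapse = ", ")))
  }
  out[is_missing] <- NA_real_
  out
}

read_delim_chr <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    na = character(), progress = FALSE,
                    show_col_types = FALSE)
}

#' Read a delimited expression matrix
#'
#' Reads a TSV or CSV expression matrix (dialect sniffed from the file
#' extension) with a header row and a leading identifier column, resolves a
#' binary label for every sample, and returns the canonical samples-in-rows
#' [ito_dataset()]. The tokens `""`, `"NA"`, `"NaN"` and `"null"`
#' (case-insensitive) are read as missing; any other non-numeric cell is an
#' error.
#'
#' @param path Path to the delimited file.
#' @param orientation `"samples_in_rows"` (default) or `"features_in_rows"`.
#' @param label_source Either the name of a label column (samples in rows) /
#'   label row (features in rows) inside the file, or the path to a sidecar
#'   two-column delimited file mapping sample id to label.
#' @param positive_label The label value mapped to class 1; all other values
#'   map to 0.
#' @return An [ito_dataset()].
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("samples_in_rows", "features_in_rows"),
                                   label_source, positive_label) {
  orientation <- match.arg(orientation)
  raw <- read_delim_chr(path)
  if (ncol(raw) < 2L) abort("expected an identifier column plus data columns.")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) abort(sprintf("duplicate identifiers in %s.", path))
  body <- raw[, -1, drop = FALSE]

  sidecar <- is.character(label_source) && file.exists(label_source) &&
    label_source != path
  label_chr <- NULL

  if (orientation == "samples_in_rows") {
    sample_ids <- ids
    if (!sidecar) {
      if (!label_source %in% names(body)) {
        abort(sprintf("label column '%s' not found.", label_source))
      }
      label_chr <- stats::setNames(as.character(body[[label_source]]), sample_ids)
      body <- body[, setdiff(names(body), label_source), drop = FALSE]
    }
    feature_ids <- names(body)
    mat <- matrix(parse_numeric_cells(as.matrix(body), path),
                  nrow = length(sample_ids),
                  dimnames = list(sample_ids, feature_ids))
  } else {
    feature_ids <- ids
    sample_ids <- names(body)
    if (!sidecar) {
      hit <- which(feature_ids == label_source)
      if (length(hit) != 1L) {
        abort(sprintf("label row '%s' not found.", label_source))
      }
      label_chr <- stats::setNames(as.character(unlist(body[hit, ])), sample_ids)
      body <- body[-hit, , drop = FALSE]
      feature_ids <- feature_ids[-hit]
    }
    mat <- t(matrix(parse_numeric_cells(as.matrix(body), path),
                    nrow = length(feature_ids),
                    dimnames = list(feature_ids, sample_ids)))
  }

  if (sidecar) {
    side <- read_delim_chr(label_source)
    if (ncol(side) < 2L) abort("label sidecar needs id and label columns.")
    label_chr <- stats::setNames(as.character(side[[2]]), as.character(side[[1]]))
  }

  missing_lbl <- setdiff(sample_ids, names(label_chr))
  if (length(missing_lbl) > 0L) {
    abort(sprintf("no label for sample(s): %s",
                  paste(utils::head(missing_lbl, 5), collapse = ", ")))
  }
  labels <- as.integer(label_chr[sample_ids] == as.character(positive_label))

  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    abort("need at least 2 samples and 2 features.")
  }
  ito_dataset(mat, labels, sample_ids = sample_ids, feature_ids = feature_ids)
}

#' Write an expression matrix to delimited text
#'
#' Inverse of [read_expression_matrix()]: writes the dataset with a header
#' row, a leading identifier column and an in-file label column (samples in
#' rows) or label row (features in rows). Values are written with 10
#' significant digits; missing cells as `NA`.
#'
#' @param dataset An [ito_dataset()].
#' @param path Output path (`.csv` writes comma-separated, anything else tab).
#' @param orientation Layout of the written file.
#' @param label_name Name used for the label column/row.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(dataset, path,
                                    orientation = c("samples_in_rows", "features_in_rows"),
                                    label_name = "class") {
  orientation <- match.arg(orientation)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  fmt <- function(v) ifelse(is.na(v), "NA", formatC(v, digits = 10, format = "g"))
  m <- dataset$matrix
  if (orientation == "samples_in_rows") {
    tbl <- data.frame(id = dataset$sample_ids,
                      lbl = as.character(dataset$labels),
                      apply(m, 2, fmt),
                      check.names = FALSE, stringsAsFactors = FALSE)
    names(tbl) <- c("sample_id", label_name, dataset$feature_ids)
  } else {
    tbl <- data.frame(id = c(label_name, dataset$feature_ids),
                      rbind(as.character(dataset$labels), apply(t(m), 2, fmt)),
                      check.names = FALSE, stringsAsFactors = FALSE)
    names(tbl) <- c("feature_id", dataset$sample_ids)
  }
  readr::write_delim(tbl, path, delim = delim, na = "NA", progress = FALSE)
  invisible(path)
}
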