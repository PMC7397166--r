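#' Specification for a synthetic HDLSS expression dataset
#'
#' Describes a two-class, high-dimension low-sample-size dataset with planted
#' signal: `n_informative` features whose class-conditional means differ by
#' `effect_size` (in within-class standard deviation units), `n_redundant`
#' noisy copies of randomly chosen informative features, and independent
#' standard-normal noise features. Missing values are planted in noise
#' features only by default, so the missing-feature exclusion rule never
#' destroys planted signal in recovery experiments. The default shape mirrors
#' a lung-toxicology benchmark cohort: 70 training / 88 validation samples
#' with a 26:44 positive:negative training split.
#'
#' @param n_train,n_valid Sample counts.
#' @param n_features Total features.
#' @param n_informative,n_redundant Planted feature counts.
#' @param effect_size Class-mean shift of informative features
#'   (within-class sd units).
#' @param positive_fraction Fraction of positive samples (exact counts by
#'   rounding).
#' @param missing_rate Per-cell missing probability within the
#'   missing-eligible features.
#' @param redundancy_noise_sd Noise sd added to redundant copies.
#' @param missing_in `"noise"` (default) or `"anywhere"`: which features may
#'   carry missing cells. Half of the eligible features are drawn as
#'   missing-prone.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_train = 70, n_valid = 88, n_features = 500,
                           n_informative = 10, n_redundant = 10,
                           effect_size = 2.0, positive_fraction = 26 / 70,
                           missing_rate = 0.05, redundancy_noise_sd = 0.3,
                           missing_in = c("noise", "anywhere"), seed = 1L) {
  missing_in <- match.arg(missing_in)
  spec <- list(n_train = as.integer(n_train), n_valid = as.integer(n_valid),
               n_features = as.integer(n_features),
               n_informative = as.integer(n_informative),
               n_redundant = as.integer(n_redundant),
               effect_size = effect_size,
               positive_fraction = positive_fraction,
               missing_rate = missing_rate,
               redundancy_noise_sd = redundancy_noise_sd,
               missing_in = missing_in, seed = as.integer(seed))
  if (spec$n_informative + spec$n_redundant > spec$n_features) {
    abort("n_informative + n_redundant must not exceed n_features.")
  }
  if (any(c(spec$n_train, spec$n_valid, spec$n_features) <= 0)) {
    abort("counts must be positive.")
  }
  if (positive_fraction <= 0 || positive_fraction >= 1) {
    abort("positive_fraction must lie in (0, 1).")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("missing_rate must lie in [0, 1).")
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic two-class expression dataset pair
#'
#' Draws a training and a validation dataset from the identical distribution
#' described by the spec, with planted informative and redundant features at
#' randomly permuted column positions, and reports the ground truth.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `train` and `valid` [ito_dataset()]s and `truth`
#'   (character vectors `informative` and `redundant`, plus the
#'   redundant-to-source map).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nf <- spec$n_features
  ni <- spec$n_informative
  nr <- spec$n_redundant

  with_seed(spec$seed, {
    feature_ids <- sprintf("f%05d", seq_len(nf))
    slots <- sample.int(nf)
    inf_idx <- slots[seq_len(ni)]
    red_idx <- if (nr > 0) slots[ni + seq_len(nr)] else integer(0)
    noise_idx <- setdiff(seq_len(nf), c(inf_idx, red_idx))
    sources <- if (nr > 0) sample(inf_idx, nr, replace = TRUE) else integer(0)

    n_missing_prone <- floor(length(noise_idx) / 2)
    eligible <- if (spec$missing_in == "noise") {
      sample(noise_idx, n_missing_prone)
    } else {
      sample(seq_len(nf), floor(nf / 2))
    }

    draw <- function(n, prefix) {
      n_pos <- round(spec$positive_fraction * n)
      labels <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
      m <- matrix(stats::rnorm(n * nf), nrow = n)
      for (j in inf_idx) {
        m[, j] <- stats::rnorm(n, mean = spec$effect_size * labels)
      }
      for (t in seq_along(red_idx)) {
        m[, red_idx[t]] <- m[, sources[t]] +
          stats::rnorm(n, sd = spec$redundancy_noise_sd)
      }
      if (spec$missing_rate > 0 && length(eligible) > 0) {
        for (j in eligible) {
          hit <- stats::runif(n) < spec$missing_rate
          m[hit, j] <- NA_real_
        }
      }
      ito_dataset(m, labels,
                  sample_ids = sprintf("%s_s%04d", prefix, seq_len(n)),
                  feature_ids = feature_ids)
    }

    train <- draw(spec$n_train, "train")
    valid <- draw(spec$n_valid, "valid")

    list(
      train = train, valid = valid,
      truth = list(
        informative = feature_ids[inf_idx],
        redundant = feature_ids[red_idx],
        sources = stats::setNames(feature_ids[sources], feature_ids[red_idx]),
        missing_prone = feature_ids[eligible]
      )
    )
  })
}

#' Write a synthetic dataset pair to disk
#'
#' Writes `train.tsv`, `valid.tsv` (samples in rows, `class` label column)
#' and `truth.json` into a directory.
#'
#' @param sim Result of [generate_synthetic()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_synthetic <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(sim$train, file.path(out_dir, "train.tsv"))
  write_expression_matrix(sim$valid, file.path(out_dir, "valid.tsv"))
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = FALSE)
  invisible(out_dir)
}
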