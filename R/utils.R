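#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Deterministic 31-bit sub-seed from a master seed and a stream tag, so that
# independent stages (LIG sampling, FT sampling, per-soldier RNG) never share
# an RNG stream. Arithmetic stays below 2^53 so doubles are exact.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((abs(as.numeric(seed)) %% 1e6 * 69067 + h * 10007 + 12345) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopifnot_binary <- function(x, what) {
  if (!all(x %in% c(0L, 1L))) {
    abort(sprintf("`%s` must contain only 0/1 values.", what))
  }
}
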