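# Independent oracles, coded from the definitions with plain loops and
# base-R table(); deliberately share no code with the package internals.

oracle_mi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  s <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pij <- tab[i, j] / n
      if (pij > 0) {
        s <- s + pij * log(pij / ((sum(tab[i, ]) / n) * (sum(tab[, j]) / n)))
      }
    }
  }
  max(0, s)
}

oracle_discretize <- function(v, nb) {
  n <- length(v)
  out <- integer(n)
  for (i in seq_len(n)) {
    r <- sum(v < v[i]) + 1 # lowest rank among ties
    out[i] <- floor((r - 1) * nb / n)
  }
  out
}

# Exhaustive greedy selection re-evaluating every criterion from scratch at
# every step (no incremental state).
oracle_select <- function(x, y, method, k, nb = 5) {
  nb <- min(nb, nrow(x))
  d <- apply(x, 2, oracle_discretize, nb = nb)
  sel <- integer(0)
  for (step in seq_len(k)) {
    best_j <- NA_integer_
    best_crit <- -Inf
    for (j in setdiff(seq_len(ncol(x)), sel)) {
      if (length(sel) == 0L) {
        crit <- oracle_mi(d[, j], y)
      } else if (method == "mrmr") {
        red <- 0
        for (s in sel) red <- red + oracle_mi(d[, j], d[, s])
        crit <- oracle_mi(d[, j], y) - red / length(sel)
      } else if (method == "jmi") {
        crit <- 0
        for (s in sel) crit <- crit + oracle_mi(paste(d[, j], d[, s]), y)
      } else { # jmim
        crit <- Inf
        for (s in sel) crit <- min(crit, oracle_mi(paste(d[, j], d[, s]), y))
      }
      if (crit > best_crit + 1e-10) { # ties keep the lower feature index
        best_crit <- crit
        best_j <- j
      }
    }
    sel <- c(sel, best_j)
  }
  sel
}

# Minimal stand-in for a trained soldier: just the fields the ensembling
# operations consume.
stub_soldier <- function(oof, y, id = "stub") {
  list(family = id, phase = "LIG", oof = as.integer(oof),
       selection_eval = evaluate_predictions(as.integer(oof), y))
}

# Small complete dataset with a known signal feature.
tiny_dataset <- function(n = 30, nf = 8, seed = 1, signal = 0) {
  set.seed(seed)
  y <- rep_len(c(1L, 0L), n)
  m <- matrix(rnorm(n * nf), n, nf)
  if (signal > 0) m[, 1] <- m[, 1] + signal * y
  ito_dataset(m, y)
}
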