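#' Generate the attack-vector grid
#'
#' Full Cartesian product of the configured option sets, one row per attack
#' vector, in deterministic order (preprocessing varies slowest, validation
#' fastest). An attack vector assigns a soldier its full pipeline:
#' preprocessing method, feature-selection method, subset size, and
#' validation protocol.
#'
#' @param preps Character vector of preprocessing method names
#'   (`"standard"`, `"robust"`, `"quantile"`, `"none"`).
#' @param sizes Integer vector of feature-subset sizes.
#' @param fss_methods Character vector among `"mrmr"`, `"jmi"`, `"jmim"`.
#' @param validations Character vector among `"tenfold_cv"`, `"loocv"`.
#' @return An `ito_grid` tibble with columns `prep`, `fss_method`,
#'   `subset_size`, `validation`.
#' @examples
#' nrow(generate_options_grid(c("standard", "none"), c(10, 50), "mrmr", "loocv"))
#' @export
generate_options_grid <- function(preps, sizes, fss_methods, validations) {
  if (length(preps) == 0L || length(sizes) == 0L ||
      length(fss_methods) == 0L || length(validations) == 0L) {
    abort("all option sets must be nonempty.")
  }
  g <- tidyr::expand_grid(prep = as.character(preps),
                          fss_method = as.character(fss_methods),
                          subset_size = as.integer(sizes),
                          validation = as.character(validations))
  class(g) <- c("ito_grid", class(g))
  g
}

#' Randomly sample a fraction of the grid
#'
#' Uniform sample without replacement of `floor(fraction * nrow(grid))`
#' attack vectors (at least 1), reproducible under `seed`.
#'
#' @param grid An `ito_grid` (or any tibble of attack vectors).
#' @param fraction Fraction in (0, 1].
#' @param seed Integer seed for the draw.
#' @return The sampled subset, in draw order.
#' @export
sample_grid <- function(grid, fraction = 0.5, seed = 1L) {
  if (fraction <= 0 || fraction > 1) abort("`fraction` must lie in (0, 1].")
  m <- max(1L, floor(fraction * nrow(grid)))
  idx <- with_seed(seed, sample.int(nrow(grid), m))
  grid[idx, , drop = FALSE]
}

# ---- cross-validation machinery --------------------------------------------

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin, so fold sizes and class balance are as even as possible.
make_folds <- function(y, validation, seed) {
  n <- length(y)
  if (validation == "loocv") return(as.list(seq_len(n)))
  if (validation != "tenfold_cv") {
    abort(sprintf("unknown validation method '%s'.", validation))
  }
  k <- min(10L, min(table(y)))
  if (k < 2L) abort("too few samples per class for cross-validation.")
  assign_fold <- integer(n)
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      assign_fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) which(assign_fold == f))
}

# Pooled out-of-fold predictions for one classifier configuration.
oof_predictions <- function(x, y, family, params, folds, seed) {
  pred <- integer(length(y))
  for (i in seq_along(folds)) {
    hold <- folds[[i]]
    model <- family$fit(x[-hold, , drop = FALSE], y[-hold], params,
                        seed = derive_seed(seed, paste0("fold", i)))
    pred[hold] <- family$predict(model, x[hold, , drop = FALSE])
  }
  pred
}

# ---- soldier construction ---------------------------------------------------

# Shared pipeline front end: missing-feature exclusion, scaling, FSS.
# Everything is fit on the training data only; the returned context carries
# what evaluate_on_holdout() needs to project new data into the same space.
prepare_pipeline <- function(train, av, n_bins) {
  excl <- exclude_missing_features(train)
  scaler <- fit_scaler(excl$train, av$prep)
  scaled <- apply_scaler(scaler, excl$train)
  k <- av$subset_size
  if (k > n_features(scaled)) {
    warn(sprintf("subset_size %d exceeds %d surviving features; clamped.",
                 k, n_features(scaled)))
    k <- n_features(scaled)
  }
  sel <- select_features(scaled, av$fss_method, k, n_bins)
  sub <- select_dataset_features(scaled, sel$feature_id)
  list(excl = excl, scaler = scaler, selection = sel,
       x = sub$matrix, y = sub$labels)
}

new_soldier <- function(phase, family_name, av, best_params, eval_row, oof,
                        model, ctx, seed, n_bins) {
  structure(
    list(phase = phase, family = family_name,
         attack_vector = tibble::as_tibble(av),
         best_params = best_params,
         selection_eval = eval_row, oof = oof, model = model,
         kept_features = ctx$excl$kept, medians = ctx$excl$medians,
         scaler = ctx$scaler, selection = ctx$selection,
         seed = seed, n_bins = n_bins),
    class = "ito_soldier"
  )
}

#' @export
print.ito_soldier <- function(x, ...) {
  cat(sprintf(
    "<ito_soldier> %s/%s  av=(%s, %s, k=%d, %s)  rho=%.4f (mcc=%.3f, acc=%.3f)\n",
    x$phase, x$family, x$attack_vector$prep, x$attack_vector$fss_method,
    x$attack_vector$subset_size, x$attack_vector$validation,
    x$selection_eval$rho, x$selection_eval$mcc, x$selection_eval$accuracy))
  invisible(x)
}

#' Train a first-wave (LIG) soldier
#'
#' Runs the full pipeline for one attack vector — missing-feature exclusion,
#' scaling fit on the training set, mutual-information feature selection —
#' then trains a parameter-free classifier with default settings. The
#' soldier's selection score is computed from pooled out-of-fold predictions
#' under the attack vector's own validation protocol (stratified 10-fold CV
#' or LOOCV) on the training data; a final predictor is refit on the full
#' training set for later voting.
#'
#' @param train Training [ito_dataset()] (both classes present).
#' @param av One-row attack vector (see [generate_options_grid()]).
#' @param family Name of a registered parameter-free family.
#' @param seed Integer seed (folds and any stochastic fitting derive from it).
#' @param n_bins Discretization bins for feature selection.
#' @return An `ito_soldier`.
#' @export
train_lig_soldier <- function(train, av, family, seed = 1L, n_bins = 5) {
  fam <- get_family(family, "lig")
  av <- as.list(av)
  ctx <- prepare_pipeline(train, av, n_bins)
  folds <- make_folds(ctx$y, av$validation, derive_seed(seed, "folds"))
  oof <- oof_predictions(ctx$x, ctx$y, fam, list(), folds, seed)
  eval_row <- evaluate_predictions(oof, ctx$y)
  model <- fam$fit(ctx$x, ctx$y, list(), seed = derive_seed(seed, "final"))
  new_soldier("LIG", family, av, list(), eval_row, oof, model, ctx, seed, n_bins)
}

#' Train a second-wave (FT) soldier with grid search
#'
#' Same pipeline as [train_lig_soldier()], but the classifier is
#' parameterized: every candidate parameter assignment in the grid (or a
#' random subset of it) is scored by the efficiency index rho of its pooled
#' out-of-fold predictions, and the soldier carries the winning assignment.
#' Ties break toward higher MCC, then first-seen grid order.
#'
#' @inheritParams train_lig_soldier
#' @param family Name of a registered parameterized (FT) family.
#' @param param_grid Named list of parameter value vectors; defaults to the
#'   family's registered grid.
#' @param search `"exhaustive"` (every assignment) or `"random"`
#'   (`n_random` assignments drawn without replacement).
#' @param n_random Number of assignments for random search.
#' @return An `ito_soldier` with `best_params` set to the winning assignment.
#' @export
train_ft_soldier <- function(train, av, family, param_grid = NULL,
                             search = c("exhaustive", "random"),
                             n_random = 10L, seed = 1L, n_bins = 5) {
  fam <- get_family(family, "ft")
  search <- match.arg(search)
  av <- as.list(av)
  grid <- param_grid %||% fam$default_grid
  if (is.null(grid) || length(grid) == 0L || prod(lengths(grid)) == 0) {
    abort("empty parameter grid.")
  }
  candidates <- do.call(tidyr::expand_grid, grid)
  if (search == "random" && n_random < nrow(candidates)) {
    idx <- with_seed(derive_seed(seed, "ftsearch"),
                     sort(sample.int(nrow(candidates), n_random)))
    candidates <- candidates[idx, , drop = FALSE]
  }

  ctx <- prepare_pipeline(train, av, n_bins)
  folds <- make_folds(ctx$y, av$validation, derive_seed(seed, "folds"))

  best <- NULL
  for (i in seq_len(nrow(candidates))) {
    params <- as.list(candidates[i, ])
    oof <- oof_predictions(ctx$x, ctx$y, fam, params, folds,
                           derive_seed(seed, paste0("cand", i)))
    ev <- evaluate_predictions(oof, ctx$y)
    if (is.null(best) || ev$rho > best$ev$rho ||
        (ev$rho == best$ev$rho && ev$mcc > best$ev$mcc)) {
      best <- list(params = params, ev = ev, oof = oof, i = i)
    }
  }
  model <- fam$fit(ctx$x, ctx$y, best$params,
                   seed = derive_seed(seed, paste0("final", best$i)))
  new_soldier("FT", family, av, best$params, best$ev, best$oof, model, ctx,
              seed, n_bins)
}

#' Evaluate a soldier or ensemble on held-out data
#'
#' Projects the holdout dataset through the soldier's fitted preprocessing
#' (training-feature survival, training-median imputation, the fitted
#' scaler), restricts to its selected features, predicts, and scores. For an
#' ensemble, member predictions are combined by [majority_vote()] first.
#'
#' @param object An `ito_soldier` or `ito_ensemble`.
#' @param holdout An [ito_dataset()] whose features are alignable to the
#'   object's training feature space.
#' @return A one-row evaluation tibble (see [evaluate_predictions()]) with
#'   the prediction vector attached as attribute `"predictions"`.
#' @export
evaluate_on_holdout <- function(object, holdout) {
  UseMethod("evaluate_on_holdout")
}

predict_soldier <- function(soldier, holdout) {
  missing <- setdiff(soldier$kept_features, holdout$feature_ids)
  if (length(missing) > 0L) {
    abort(sprintf("holdout lacks %d features required by the soldier.",
                  length(missing)))
  }
  m <- holdout$matrix[, soldier$kept_features, drop = FALSE]
  nas <- which(is.na(m), arr.ind = TRUE)
  if (nrow(nas) > 0L) m[nas] <- soldier$medians[nas[, 2]]
  ds <- ito_dataset(m, holdout$labels, holdout$sample_ids,
                    soldier$kept_features)
  scaled <- apply_scaler(soldier$scaler, ds)
  sub <- select_dataset_features(scaled, soldier$selection$feature_id)
  fam <- get_family(soldier$family)
  fam$predict(soldier$model, sub$matrix)
}

#' @export
evaluate_on_holdout.ito_soldier <- function(object, holdout) {
  pred <- predict_soldier(object, holdout)
  out <- evaluate_predictions(pred, holdout$labels)
  attr(out, "predictions") <- pred
  out
}
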