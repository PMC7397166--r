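#' Run configuration for the two-phase ensemble pipeline
#'
#' Collects every tunable of the pipeline with defaults matching the
#' published study configuration: four preprocessing options, the canonical
#' subset sizes, the three mutual-information selection criteria, both
#' validation protocols, the tree-family LIG trio, the three grid-tuned FT
#' families, half-grid random sampling, and top-33% epsilon filtering.
#'
#' @param preps,subset_sizes,fss_methods,validations Option sets defining
#'   the attack-vector grid (see [generate_options_grid()]).
#' @param lig_families Registered parameter-free family names.
#' @param ft_families Registered parameterized family names.
#' @param ft_grids Optional named list of parameter grids overriding the
#'   registered defaults, keyed by family name.
#' @param ft_search `"exhaustive"` or `"random"` grid search for FT tuning.
#' @param ft_n_random Assignments drawn per soldier under random search.
#' @param grid_fraction Fraction of the attack-vector grid sampled per phase.
#' @param epsilon_lig,epsilon_ft Optional explicit fitness thresholds
#'   (override fraction-based filtering).
#' @param fraction Top fraction admitted when epsilons are not given.
#' @param final_strategy Final-ensemble strategy `"a"`, `"b"` or `"c"`.
#' @param strict_improvement Require strict rho improvement during greedy
#'   ensembling.
#' @param n_bins Discretization bins for feature selection.
#' @param max_features Guard: refuse wider inputs unless `force = TRUE` in
#'   [run_ito()] (mutual-information selection over very wide matrices is a
#'   long-haul computation).
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Optional output directory; when set, the first-wave
#'   ensemble is serialized there before second-wave training begins.
#' @return An `ito_config` list.
#' @export
run_config <- function(preps = c("quantile", "robust", "standard", "none"),
                       subset_sizes = c(10, 50, 100, 150, 200, 250),
                       fss_methods = c("mrmr", "jmi", "jmim"),
                       validations = c("tenfold_cv", "loocv"),
                       lig_families = c("decision_tree", "adaboost", "extra_trees"),
                       ft_families = c("random_forest", "svm", "mlp"),
                       ft_grids = NULL,
                       ft_search = "exhaustive", ft_n_random = 10L,
                       grid_fraction = 0.5,
                       epsilon_lig = NULL, epsilon_ft = NULL, fraction = 0.33,
                       final_strategy = "c", strict_improvement = FALSE,
                       n_bins = 5, max_features = 5000, seed = 1L,
                       out_dir = NULL) {
  cfg <- list(preps = preps, subset_sizes = subset_sizes,
              fss_methods = fss_methods, validations = validations,
              lig_families = lig_families, ft_families = ft_families,
              ft_grids = ft_grids, ft_search = ft_search,
              ft_n_random = as.integer(ft_n_random),
              grid_fraction = grid_fraction,
              epsilon_lig = epsilon_lig, epsilon_ft = epsilon_ft,
              fraction = fraction, final_strategy = final_strategy,
              strict_improvement = strict_improvement,
              n_bins = n_bins, max_features = max_features,
              seed = as.integer(seed), out_dir = out_dir)
  for (fam in cfg$lig_families) get_family(fam, "lig")
  for (fam in cfg$ft_families) get_family(fam, "ft")
  if (cfg$grid_fraction <= 0 || cfg$grid_fraction > 1) {
    abort("grid_fraction must lie in (0, 1].")
  }
  if (!cfg$final_strategy %in% c("a", "b", "c")) {
    abort("final_strategy must be one of 'a', 'b', 'c'.")
  }
  structure(cfg, class = "ito_config")
}

train_phase <- function(train, avs, families, phase, config) {
  soldiers <- list()
  i <- 0L
  for (r in seq_len(nrow(avs))) {
    av <- avs[r, ]
    for (fam in families) {
      i <- i + 1L
      seed_i <- derive_seed(config$seed, paste0(phase, "-soldier-", i))
      soldiers[[i]] <- if (phase == "lig") {
        train_lig_soldier(train, av, fam, seed = seed_i,
                          n_bins = config$n_bins)
      } else {
        train_ft_soldier(train, av, fam,
                         param_grid = config$ft_grids[[fam]],
                         search = config$ft_search,
                         n_random = config$ft_n_random,
                         seed = seed_i, n_bins = config$n_bins)
      }
    }
  }
  soldiers
}

#' Run the full two-phase infiltration pipeline
#'
#' Executes the complete algorithm: attack-vector grid generation, random
#' half-grid sampling per phase, first-wave (LIG) training and filtering,
#' greedy first-wave ensembling (available — and, when `out_dir` is set,
#' serialized — before any second-wave training starts), second-wave (FT)
#' grid-search training and filtering, second-wave ensembling, the combined
#' ensemble (plain union of the two phase ensembles) and the tuned final
#' ensemble under the configured strategy. Every soldier and ensemble is then
#' evaluated on the validation dataset, and summary/improvement tables are
#' assembled.
#'
#' @param train,valid Training and validation [ito_dataset()]s sharing one
#'   feature space.
#' @param config An [run_config()].
#' @param force Bypass the `max_features` width guard.
#' @return An `ito_report` list: `soldiers` (list), `ensembles`
#'   (`lig`/`ft`/`combined`/`final`), tibbles `soldier_summary`, `summary`,
#'   `improvement`, the attained `epsilons`, the sampled grids, config and
#'   seed.
#' @export
run_ito <- function(train, valid, config = run_config(), force = FALSE) {
  stopifnot(inherits(train, "ito_dataset"), inherits(valid, "ito_dataset"))
  if (!identical(train$feature_ids, valid$feature_ids)) {
    abort("train and valid must share one feature space.")
  }
  if (length(unique(train$labels)) < 2L) {
    abort("training data must contain both classes.")
  }
  if (n_features(train) > config$max_features && !force) {
    abort(sprintf(
      "input has %d features (> max_features = %d); pass force = TRUE for long-haul runs.",
      n_features(train), config$max_features))
  }

  grid <- generate_options_grid(config$preps, config$subset_sizes,
                                config$fss_methods, config$validations)
  t_lig <- sample_grid(grid, config$grid_fraction,
                       derive_seed(config$seed, "lig-grid"))
  lig_soldiers <- train_phase(train, t_lig, config$lig_families, "lig", config)
  lig_filtered <- filter_successful(lig_soldiers, config$epsilon_lig,
                                    config$fraction)
  lig_ensemble <- if (length(lig_filtered) > 0L) {
    build_greedy_ensemble(lig_filtered, train$labels,
                          config$strict_improvement, "lig")
  } else {
    warn("no successful first-wave soldiers; continuing with an empty LIG phase.")
    NULL
  }

  # two-phase availability: the first-wave ensemble is on disk before any
  # second-wave training happens
  if (!is.null(config$out_dir) && !is.null(lig_ensemble)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      ensemble_record(lig_ensemble, lig_soldiers),
      file.path(config$out_dir, "lig_ensemble.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  t_ft <- sample_grid(grid, config$grid_fraction,
                      derive_seed(config$seed, "ft-grid"))
  ft_soldiers <- train_phase(train, t_ft, config$ft_families, "ft", config)
  ft_filtered <- filter_successful(ft_soldiers, config$epsilon_ft,
                                   config$fraction)
  ft_ensemble <- if (length(ft_filtered) > 0L) {
    build_greedy_ensemble(ft_filtered, train$labels,
                          config$strict_improvement, "ft")
  } else NULL

  if (length(lig_filtered) == 0L && length(ft_filtered) == 0L) {
    abort("no successful soldiers in either phase; cannot build an ensemble.")
  }

  combined <- build_final_ensemble(lig_filtered, ft_filtered, train$labels,
                                   strategy = "a",
                                   lig_ensemble = lig_ensemble,
                                   ft_ensemble = ft_ensemble)
  combined$strategy <- "combined"
  final <- build_final_ensemble(lig_filtered, ft_filtered, train$labels,
                                strategy = config$final_strategy,
                                strict_improvement = config$strict_improvement,
                                lig_ensemble = lig_ensemble,
                                ft_ensemble = ft_ensemble)

  soldiers <- c(lig_soldiers, ft_soldiers)
  holdout_evals <- lapply(soldiers, evaluate_on_holdout, holdout = valid)
  ensembles <- list(lig = lig_ensemble, ft = ft_ensemble,
                    combined = combined, final = final)
  ens_holdout <- lapply(ensembles, function(e) {
    if (is.null(e)) NULL else evaluate_on_holdout(e, valid)
  })

  report <- structure(
    list(soldiers = soldiers, holdout_evals = holdout_evals,
         ensembles = ensembles, ensemble_holdout = ens_holdout,
         lig_filtered = lig_filtered, ft_filtered = ft_filtered,
         epsilons = c(lig = attr(lig_filtered, "epsilon"),
                      ft = attr(ft_filtered, "epsilon")),
         grids = list(full_size = nrow(grid), lig = t_lig, ft = t_ft),
         config = config, seed = config$seed),
    class = "ito_report"
  )
  tabs <- make_summary_tables(report)
  report$summary <- tabs$summary
  report$improvement <- tabs$improvement
  report$soldier_summary <- soldier_summary(report)
  report
}

#' @export
print.ito_report <- function(x, ...) {
  cat(sprintf("<ito_report> %d soldiers (%d LIG, %d FT), seed %d\n",
              length(x$soldiers),
              sum(vapply(x$soldiers, function(s) s$phase == "LIG", logical(1))),
              sum(vapply(x$soldiers, function(s) s$phase == "FT", logical(1))),
              x$seed))
  print(x$summary)
  invisible(x)
}

soldier_summary <- function(report) {
  purrr::map2_dfr(report$soldiers, report$holdout_evals, function(s, h) {
    dplyr::bind_cols(
      tibble(phase = s$phase, family = s$family),
      s$attack_vector,
      dplyr::rename_with(s$selection_eval[, c("accuracy", "mcc", "rho")],
                         ~ paste0("selection_", .x)),
      dplyr::rename_with(h[, c("accuracy", "mcc", "rho")],
                         ~ paste0("holdout_", .x))
    )
  })
}

#' Summary and improvement tables for a finished run
#'
#' Builds the canonical nine-column summary — each measure (accuracy, MCC,
#' efficiency index) for the average and best filtered member of each phase,
#' the two phase ensembles, the combined ensemble and the tuned final
#' ensemble, all on holdout predictions — and the improvement matrix
#' `100 * (final - baseline) / final` of the tuned column over the six
#' canonical baselines, rounded to 2 decimals.
#'
#' @param report An `ito_report` from [run_ito()].
#' @return A list with tibbles `summary` and `improvement`.
#' @export
make_summary_tables <- function(report) {
  hold_for <- function(soldier) {
    i <- which(vapply(report$soldiers, identical, logical(1), soldier))[1]
    report$holdout_evals[[i]]
  }
  member_cols <- function(filtered) {
    if (length(filtered) == 0L) {
      return(list(avg = rep(NA_real_, 3), best = rep(NA_real_, 3)))
    }
    evs <- purrr::map_dfr(filtered, hold_for)
    sel <- purrr::map_dfr(filtered, "selection_eval")
    best_i <- which.max(sel$rho)
    list(avg = c(mean(evs$accuracy), mean(evs$mcc), mean(evs$rho)),
         best = c(evs$accuracy[best_i], evs$mcc[best_i], evs$rho[best_i]))
  }
  ens_col <- function(tag) {
    h <- report$ensemble_holdout[[tag]]
    if (is.null(h)) rep(NA_real_, 3) else c(h$accuracy, h$mcc, h$rho)
  }
  lig <- member_cols(report$lig_filtered)
  ft <- member_cols(report$ft_filtered)
  summary <- tibble(
    measure = c("accuracy", "mcc", "rho"),
    lig_member = lig$avg, lig_member_best = lig$best,
    ft_member = ft$avg, ft_member_best = ft$best,
    lig_ensemble = ens_col("lig"), ft_ensemble = ens_col("ft"),
    combined = ens_col("combined"), ito_tuned = ens_col("final")
  )
  list(summary = summary, improvement = improvement_table(summary))
}

#' Improvement matrix over the tuned column
#'
#' For each measure row, the percentage `100 * (final - baseline) / final`
#' of the tuned final column over each baseline column, rounded to two
#' decimals. Accepts any summary tibble with a `measure` column, baseline
#' columns, and the final column.
#'
#' @param summary Summary tibble (see [make_summary_tables()]).
#' @param final_col Name of the final (reference) column.
#' @param baseline_cols Baseline column names; defaults to the six canonical
#'   ones present in `summary`.
#' @return A tibble: `measure` plus one improvement column per baseline.
#' @export
improvement_table <- function(summary, final_col = "ito_tuned",
                              baseline_cols = NULL) {
  if (is.null(baseline_cols)) {
    baseline_cols <- intersect(
      c("lig_member", "ft_member", "lig_ensemble", "ft_ensemble", "combined"),
      names(summary))
  }
  out <- tibble(measure = summary$measure)
  for (col in baseline_cols) {
    out[[col]] <- round(
      improvement_percentage(summary[[final_col]], summary[[col]]), 2)
  }
  out
}
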