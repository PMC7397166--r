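soldier_record <- function(s, holdout_eval = NULL) {
  rec <- list(
    phase = s$phase, family = s$family,
    attack_vector = as.list(s$attack_vector),
    best_params = s$best_params,
    selected_features = s$selection$feature_id,
    selection_eval = as.list(s$selection_eval)
  )
  if (!is.null(holdout_eval)) {
    rec$holdout_eval <- as.list(holdout_eval[, c("accuracy", "mcc", "rho",
                                                 "n_evaluated")])
  }
  rec
}

ensemble_record <- function(ens, soldiers) {
  if (is.null(ens)) return(NULL)
  idx <- vapply(ens$members, function(m) {
    which(vapply(soldiers, identical, logical(1), m))[1]
  }, integer(1))
  list(
    strategy = ens$strategy,
    member_indices = idx,
    rho_trajectory = ens$rho_trajectory,
    selection_eval = as.list(ens$selection_eval)
  )
}

#' Write a run report to disk
#'
#' Writes three artifacts into a directory: `report.json` (every soldier's
#' attack vector, tuned parameters, selected features and metrics, plus all
#' ensemble memberships and trajectories), `summary.tsv` (one row per
#' best-LIG-member / best-FT-member / LIG ensemble / FT ensemble / combined /
#' final, with accuracy, MCC and rho on both the selection and holdout
#' protocols; unavailable entries are `NA`), and `improvements.tsv` (the
#' improvement matrix).
#'
#' @param report An `ito_report` from [run_ito()].
#' @param out_dir Output directory (created if needed; unwritable is an
#'   error).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) abort(sprintf("cannot create '%s'.", out_dir))
  if (file.access(out_dir, 2) != 0) abort(sprintf("'%s' is not writable.", out_dir))

  payload <- report_content(report)
  jsonlite::write_json(payload, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  readr::write_tsv(summary_rows(report), file.path(out_dir, "summary.tsv"),
                   na = "NA", progress = FALSE)
  readr::write_tsv(report$improvement, file.path(out_dir, "improvements.tsv"),
                   na = "NA", progress = FALSE)
  invisible(out_dir)
}

# JSON-serializable content of a report (also the round-trip contract).
report_content <- function(report) {
  cfg <- report$config
  cfg$out_dir <- NULL
  list(
    seed = report$seed,
    grid_full_size = report$grids$full_size,
    epsilons = as.list(report$epsilons),
    soldiers = purrr::map2(report$soldiers, report$holdout_evals,
                           soldier_record),
    ensembles = purrr::map(report$ensembles, ensemble_record,
                           soldiers = report$soldiers),
    summary = as.list(report$summary),
    improvement = as.list(report$improvement),
    config = cfg[c("preps", "subset_sizes", "fss_methods", "validations",
                   "lig_families", "ft_families", "grid_fraction",
                   "fraction", "final_strategy", "n_bins")]
  )
}

summary_rows <- function(report) {
  sel_of <- function(obj) {
    if (is.null(obj)) return(tibble(accuracy = NA_real_, mcc = NA_real_,
                                    rho = NA_real_))
    obj$selection_eval[, c("accuracy", "mcc", "rho")]
  }
  hold_of <- function(h) {
    if (is.null(h)) return(tibble(accuracy = NA_real_, mcc = NA_real_,
                                  rho = NA_real_))
    h[, c("accuracy", "mcc", "rho")]
  }
  best_of <- function(filtered) {
    if (length(filtered) == 0L) return(list(s = NULL, h = NULL))
    sel <- purrr::map_dfr(filtered, "selection_eval")
    best <- filtered[[which.max(sel$rho)]]
    i <- which(vapply(report$soldiers, identical, logical(1), best))[1]
    list(s = best, h = report$holdout_evals[[i]])
  }
  bl <- best_of(report$lig_filtered)
  bf <- best_of(report$ft_filtered)
  rows <- list(
    lig_member_best = list(sel_of(bl$s), hold_of(bl$h)),
    ft_member_best = list(sel_of(bf$s), hold_of(bf$h)),
    lig_ensemble = list(sel_of(report$ensembles$lig),
                        hold_of(report$ensemble_holdout$lig)),
    ft_ensemble = list(sel_of(report$ensembles$ft),
                       hold_of(report$ensemble_holdout$ft)),
    combined = list(sel_of(report$ensembles$combined),
                    hold_of(report$ensemble_holdout$combined)),
    final = list(sel_of(report$ensembles$final),
                 hold_of(report$ensemble_holdout$final))
  )
  purrr::imap_dfr(rows, function(parts, nm) {
    dplyr::bind_cols(
      tibble(entity = nm),
      dplyr::rename_with(parts[[1]], ~ paste0("selection_", .x)),
      dplyr::rename_with(parts[[2]], ~ paste0("holdout_", .x))
    )
  })
}

#' Read back a written report
#'
#' Parses `report.json` written by [write_report()] into the same list
#' structure returned by the serializer, so written and re-read content are
#' equal.
#'
#' @param path Path to `report.json` (or a directory containing it).
#' @return The report content list.
#' @export
read_report <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "report.json")
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
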