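#' Filter and rank successful soldiers
#'
#' A soldier is "successful" when its selection MCC is strictly positive
#' (better than a random guess) and its efficiency index passes the strict
#' fitness test `rho > epsilon`. The threshold is either supplied directly
#' (as when reproducing a known epsilon) or computed with
#' [epsilon_for_fraction()] so that at least the top `fraction` of the
#' MCC-positive soldiers pass. Survivors are ranked by rho, with ties broken
#' by MCC, then accuracy, then stable input order.
#'
#' @param soldiers List of `ito_soldier` objects with selection evaluations.
#' @param epsilon Optional explicit threshold; overrides `fraction`.
#' @param fraction Top fraction to admit when `epsilon` is not given.
#' @return A ranked list of soldiers with attribute `"epsilon"`; possibly
#'   empty.
#' @export
filter_successful <- function(soldiers, epsilon = NULL, fraction = 0.33) {
  stats_tbl <- purrr::map_dfr(soldiers, "selection_eval")
  eligible <- which(stats_tbl$mcc > 0)
  if (length(eligible) == 0L) {
    return(structure(list(), epsilon = epsilon %||% NA_real_))
  }
  rhos <- stats_tbl$rho[eligible]
  if (is.null(epsilon)) {
    epsilon <- epsilon_for_fraction(rhos, fraction)$epsilon
  }
  pass <- eligible[rhos > epsilon]
  ord <- order(-stats_tbl$rho[pass], -stats_tbl$mcc[pass],
               -stats_tbl$accuracy[pass], pass)
  structure(soldiers[pass[ord]], epsilon = epsilon)
}

#' Majority vote over member predictions
#'
#' Per-sample modal prediction of the members. An exact tie is decided by
#' the member with the highest efficiency index — the most trusted voter.
#'
#' @param member_predictions Binary matrix, members in rows, samples in
#'   columns.
#' @param member_rhos Efficiency index of each member (tie-break weights).
#' @return Integer 0/1 vector, one prediction per sample.
#' @export
majority_vote <- function(member_predictions, member_rhos) {
  if (is.vector(member_predictions)) {
    member_predictions <- matrix(member_predictions, nrow = 1)
  }
  if (nrow(member_predictions) == 0L) abort("need at least one member.")
  share <- colMeans(member_predictions)
  out <- as.integer(share > 0.5)
  tie <- which(share == 0.5)
  if (length(tie) > 0L) {
    out[tie] <- member_predictions[which.max(member_rhos), tie]
  }
  out
}

new_ensemble <- function(members, trajectory, strategy, y) {
  sel_eval <- evaluate_predictions(ensemble_oof(members), y)
  structure(
    list(members = members, rho_trajectory = trajectory,
         selection_eval = sel_eval, strategy = strategy),
    class = "ito_ensemble"
  )
}

ensemble_oof <- function(members) {
  preds <- do.call(rbind, lapply(members, `[[`, "oof"))
  rhos <- vapply(members, function(s) s$selection_eval$rho, numeric(1))
  majority_vote(preds, rhos)
}

#' @export
print.ito_ensemble <- function(x, ...) {
  cat(sprintf(
    "<ito_ensemble> strategy=%s, %d members, selection rho=%.4f (mcc=%.3f, acc=%.3f)\n",
    x$strategy, length(x$members), x$selection_eval$rho,
    x$selection_eval$mcc, x$selection_eval$accuracy))
  invisible(x)
}

#' Greedy non-deteriorating majority-vote ensemble
#'
#' Starts from the top-ranked candidate and walks the ranked list: each
#' candidate is tentatively added, the ensemble's majority-vote efficiency
#' index is recomputed on the selection protocol (the members' pooled
#' out-of-fold training predictions), and the candidate is kept only if the
#' index did not deteriorate (`>=` by default, `>` when
#' `strict_improvement`). By construction the ensemble's selection rho never
#' falls below its best single member's.
#'
#' @param candidates Ranked soldier list from [filter_successful()].
#' @param y Training labels the out-of-fold predictions are scored against.
#' @param strict_improvement Require strict improvement to keep a candidate.
#' @param strategy Tag recorded on the ensemble.
#' @return An `ito_ensemble` with the accepted members (in acceptance order)
#'   and the rho trajectory across accepted additions.
#' @export
build_greedy_ensemble <- function(candidates, y, strict_improvement = FALSE,
                                  strategy = "lig") {
  if (length(candidates) == 0L) {
    abort("no successful soldiers to ensemble.")
  }
  members <- candidates[1]
  cur <- evaluate_predictions(ensemble_oof(members), y)$rho
  trajectory <- cur
  for (cand in candidates[-1]) {
    trial <- c(members, list(cand))
    new_rho <- evaluate_predictions(ensemble_oof(trial), y)$rho
    keep <- if (strict_improvement) new_rho > cur else new_rho >= cur
    if (keep) {
      members <- trial
      cur <- new_rho
      trajectory <- c(trajectory, cur)
    }
  }
  new_ensemble(members, trajectory, strategy, y)
}

#' Build the final two-phase ensemble
#'
#' Combines the filtered first-wave (LIG) and second-wave (FT) soldiers into
#' the final ensemble by one of three strategies:
#'
#' * `"a"` — union of the two phase ensembles' members, no re-selection;
#' * `"b"` — start from the lower-rho phase ensemble and offer the other
#'   ensemble's members (those whose own rho is at least the current
#'   ensemble rho), keeping non-deteriorating additions;
#' * `"c"` (default) — pool both filtered lists, re-rank by rho, and rebuild
#'   greedily from scratch. This guarantees the final selection rho is at
#'   least the best individual soldier's.
#'
#' @param lig_filtered,ft_filtered Ranked lists from [filter_successful()];
#'   at least one must be nonempty.
#' @param y Training labels.
#' @param strategy `"a"`, `"b"` or `"c"`.
#' @param strict_improvement Passed to [build_greedy_ensemble()].
#' @param lig_ensemble,ft_ensemble Optional prebuilt phase ensembles
#'   (recomputed from the filtered lists when absent); used by strategies
#'   `"a"` and `"b"`.
#' @return An `ito_ensemble` tagged `final_a`/`final_b`/`final_c`.
#' @export
build_final_ensemble <- function(lig_filtered, ft_filtered, y,
                                 strategy = c("c", "a", "b"),
                                 strict_improvement = FALSE,
                                 lig_ensemble = NULL, ft_ensemble = NULL) {
  strategy <- match.arg(strategy)
  if (length(lig_filtered) == 0L && length(ft_filtered) == 0L) {
    abort("both candidate lists are empty; no successful soldiers.")
  }
  rank_pool <- function(pool) {
    tbl <- purrr::map_dfr(pool, "selection_eval")
    ord <- order(-tbl$rho, -tbl$mcc, -tbl$accuracy, seq_along(pool))
    pool[ord]
  }
  phase_ens <- function(pool, given, tag) {
    if (!is.null(given)) return(given)
    if (length(pool) == 0L) return(NULL)
    build_greedy_ensemble(pool, y, strict_improvement, tag)
  }

  if (strategy == "c") {
    pool <- rank_pool(c(lig_filtered, ft_filtered))
    ens <- build_greedy_ensemble(pool, y, strict_improvement, "final_c")
    return(ens)
  }

  le <- phase_ens(lig_filtered, lig_ensemble, "lig")
  fe <- phase_ens(ft_filtered, ft_ensemble, "ft")
  if (is.null(le) || is.null(fe)) {
    solo <- le %||% fe
    return(new_ensemble(solo$members, solo$rho_trajectory,
                        paste0("final_", strategy), y))
  }

  if (strategy == "a") {
    members <- c(le$members, fe$members)
    ens <- new_ensemble(members, evaluate_predictions(ensemble_oof(members), y)$rho,
                        "final_a", y)
    return(ens)
  }

  # strategy b: grow the lower-rho ensemble with the other's members
  if (le$selection_eval$rho <= fe$selection_eval$rho) {
    base <- le; donor <- fe
  } else {
    base <- fe; donor <- le
  }
  members <- base$members
  cur <- evaluate_predictions(ensemble_oof(members), y)$rho
  trajectory <- cur
  for (cand in rank_pool(donor$members)) {
    if (cand$selection_eval$rho < cur) next
    trial <- c(members, list(cand))
    new_rho <- evaluate_predictions(ensemble_oof(trial), y)$rho
    keep <- if (strict_improvement) new_rho > cur else new_rho >= cur
    if (keep) {
      members <- trial
      cur <- new_rho
      trajectory <- c(trajectory, cur)
    }
  }
  new_ensemble(members, trajectory, "final_b", y)
}

#' @export
evaluate_on_holdout.ito_ensemble <- function(object, holdout) {
  preds <- do.call(rbind, lapply(object$members, predict_soldier,
                                 holdout = holdout))
  rhos <- vapply(object$members, function(s) s$selection_eval$rho, numeric(1))
  vote <- majority_vote(preds, rhos)
  out <- evaluate_predictions(vote, holdout$labels)
  attr(out, "predictions") <- vote
  out
}
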