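#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a soldier into a one-row tibble
#'
#' @param x An `ito_soldier`.
#' @param ... Unused.
#' @return A tibble with the phase, family, attack vector and selection
#'   metrics.
#' @export
tidy.ito_soldier <- function(x, ...) {
  dplyr::bind_cols(
    tibble(phase = x$phase, family = x$family),
    x$attack_vector,
    x$selection_eval[, c("accuracy", "mcc", "rho")]
  )
}

#' Tidy an ensemble into its member table
#'
#' @param x An `ito_ensemble`.
#' @param ... Unused.
#' @return A tibble, one row per member in acceptance order.
#' @export
tidy.ito_ensemble <- function(x, ...) {
  dplyr::bind_cols(
    tibble(position = seq_along(x$members)),
    purrr::map_dfr(x$members, tidy)
  )
}

#' One-row ensemble summary
#'
#' @param x An `ito_ensemble`.
#' @param ... Unused.
#' @return A tibble with strategy, size and selection metrics.
#' @export
glance.ito_ensemble <- function(x, ...) {
  dplyr::bind_cols(
    tibble(strategy = x$strategy, n_members = length(x$members)),
    x$selection_eval[, c("accuracy", "mcc", "rho")]
  )
}

#' Tidy a run report into the per-soldier table
#'
#' @param x An `ito_report`.
#' @param ... Unused.
#' @return The per-soldier summary tibble (selection and holdout metrics).
#' @export
tidy.ito_report <- function(x, ...) x$soldier_summary

#' One-row report summary
#'
#' @param x An `ito_report`.
#' @param ... Unused.
#' @return A tibble with soldier counts, final-ensemble size and final
#'   holdout metrics.
#' @export
glance.ito_report <- function(x, ...) {
  h <- x$ensemble_holdout$final
  tibble(
    n_soldiers = length(x$soldiers),
    n_lig_filtered = length(x$lig_filtered),
    n_ft_filtered = length(x$ft_filtered),
    final_n_members = length(x$ensembles$final$members),
    final_holdout_accuracy = h$accuracy,
    final_holdout_mcc = h$mcc,
    final_holdout_rho = h$rho
  )
}

#' Plot the greedy rho trajectory of an ensemble
#'
#' @param object An `ito_ensemble`.
#' @param ... Unused.
#' @return A ggplot of the efficiency index after each accepted addition.
#' @export
autoplot.ito_ensemble <- function(object, ...) {
  df <- tibble(accepted = seq_along(object$rho_trajectory),
               rho = object$rho_trajectory)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accepted, y = .data$rho)) +
    ggplot2::geom_step() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "accepted members", y = expression(rho),
                  title = sprintf("Greedy ensemble trajectory (%s)",
                                  object$strategy)) +
    ggplot2::theme_minimal()
}

#' Plot ranked soldier efficiency for a run
#'
#' @param object An `ito_report`.
#' @param ... Unused.
#' @return A ggplot of per-soldier selection rho, ranked within phase.
#' @export
autoplot.ito_report <- function(object, ...) {
  df <- object$soldier_summary |>
    dplyr::group_by(.data$phase) |>
    dplyr::arrange(dplyr::desc(.data$selection_rho), .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$selection_rho,
                                   colour = .data$family)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ .data$phase, scales = "free_x") +
    ggplot2::labs(x = "soldier rank", y = expression(rho)) +
    ggplot2::theme_minimal()
}
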