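# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a grid-search fit
#'
#' @param x A `matg_fit` from [grid_fit()].
#' @param ... Unused.
#' @return The full grid ranked by full-window RMSD (ties toward higher `r`),
#'   one row per grid point with per-window `r` and `rmsd` columns.
#' @export
tidy.matg_fit <- function(x, ...) {
  dplyr::arrange(x$results, .data$rmsd_full, dplyr::desc(.data$r_full))
}

#' Glance at a grid-search fit
#'
#' @param x A `matg_fit`.
#' @param ... Unused.
#' @return A one-row tibble: the winning parameters plus `r` and `rmsd` for the
#'   full, phase-1 and phase-2 windows.
#' @export
glance.matg_fit <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    variant = x$variant,
    !!!x$best_params,
    r_full = m$r[m$window == "full"],
    rmsd_full = m$rmsd[m$window == "full"],
    r_phase1 = m$r[m$window == "phase1"],
    rmsd_phase1 = m$rmsd[m$window == "phase1"],
    r_phase2 = m$r[m$window == "phase2"],
    rmsd_phase2 = m$rmsd[m$window == "phase2"]
  )
}

#' Tidy a model simulation
#'
#' @param x A `matg_sim` from [run_model_game()].
#' @param ... Unused.
#' @return The mean allocation curves: `round`, `confederate_id`, `allocation`.
#' @export
tidy.matg_sim <- function(x, ...) x$curves

#' Glance at a model simulation
#'
#' @param x A `matg_sim`.
#' @param ... Unused.
#' @return One row per confederate with mean allocations in each strategy
#'   phase.
#' @export
glance.matg_sim <- function(x, ...) {
  sw <- x$config$switch_round
  s <- dplyr::summarise(
    dplyr::group_by(x$curves, .data$confederate_id,
                    phase = ifelse(.data$round <= sw, "phase1", "phase2")),
    allocation = mean(.data$allocation), .groups = "drop"
  )
  out <- tidyr::pivot_wider(s, names_from = "phase",
                            values_from = "allocation",
                            names_prefix = "mean_allocation_")
  dplyr::mutate(out, variant = x$variant, n_runs = x$n_runs,
                .before = 1)
}

#' Plot mean allocation curves
#'
#' One panel per confederate, mean allocation by round, with a vertical line at
#' the strategy switch.
#'
#' @param object A `matg_sim` or `matg_cohort`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.matg_sim <- function(object, ...) {
  plot_allocation_curves(object$curves, object$config,
                         title = sprintf("Model mean allocations ('%s', %d runs)",
                                         object$variant, object$n_runs))
}

#' @rdname autoplot.matg_sim
#' @export
autoplot.matg_cohort <- function(object, ...) {
  plot_allocation_curves(object$curves, object$config,
                         title = sprintf("Synthetic cohort mean allocations (n = %d)",
                                         length(object$logs)))
}

#' Plot allocation curves from a tidy curve table
#'
#' @param curves Tibble with `round`, `confederate_id`, `allocation`.
#' @param config A [game_config()] (for the switch-round marker); optional.
#' @param title Plot title.
#' @return A ggplot.
#' @export
plot_allocation_curves <- function(curves, config = NULL, title = NULL) {
  p <- ggplot2::ggplot(curves,
                       ggplot2::aes(x = .data$round, y = .data$allocation)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~confederate_id,
                        labeller = ggplot2::labeller(
                          confederate_id = function(v) paste("confederate", v))) +
    ggplot2::labs(x = "round", y = "allocation (points)", title = title) +
    ggplot2::theme_minimal()
  if (!is.null(config)) {
    p <- p + ggplot2::geom_vline(xintercept = config$switch_round,
                                 linetype = "dashed", color = "grey40")
  }
  p
}

#' Plot trust and trust-invest accumulator trajectories
#'
#' @param object A `matg_trace` (see [infer_accumulators()]).
#' @param config Optional [game_config()] for the switch-round marker.
#' @param ... Unused.
#' @return A ggplot, accumulators in rows and confederates in columns.
#' @export
autoplot.matg_trace <- function(object, config = NULL, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("trust", "invest"),
                              names_to = "accumulator", values_to = "value")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$round, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(accumulator ~ confederate_id, scales = "free_y",
                        labeller = ggplot2::labeller(
                          confederate_id = function(v) paste("confederate", v))) +
    ggplot2::labs(x = "round", y = "accumulator value") +
    ggplot2::theme_minimal()
  if (!is.null(config)) {
    p <- p + ggplot2::geom_vline(xintercept = config$switch_round,
                                 linetype = "dashed", color = "grey40")
  }
  p
}

#' Plot a fit against its target
#'
#' Overlays the winning grid point's mean model curves on the target curves.
#'
#' @param object A `matg_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.matg_fit <- function(object, ...) {
  both <- dplyr::bind_rows(
    dplyr::mutate(object$best_curves, series = "model"),
    dplyr::mutate(object$target_curves, series = "target")
  )
  ggplot2::ggplot(both, ggplot2::aes(x = .data$round, y = .data$allocation,
                                     linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~confederate_id,
                        labeller = ggplot2::labeller(
                          confederate_id = function(v) paste("confederate", v))) +
    ggplot2::geom_vline(xintercept = object$config$switch_round,
                        linetype = "dotted", color = "grey40") +
    ggplot2::labs(x = "round", y = "allocation (points)",
                  title = sprintf("'%s' fit (full-window RMSD %.2f)",
                                  object$variant,
                                  object$metrics$rmsd[object$metrics$window == "full"])) +
    ggplot2::theme_minimal()
}
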