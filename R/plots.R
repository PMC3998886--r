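#' Plot compartment trajectories
#'
#' Cell counts over time per compartment (log10 scale), line type by
#' lineage -- the standard disease-course panel.
#'
#' @param object An `mdsim_trajectory`.
#' @param log10 Use a log10 count axis (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mdsim_trajectory <- function(object, log10 = TRUE, ...) {
  df <- dplyr::filter(tidy(object), .data$count > 0)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_years, .data$count,
                                        colour = .data$compartment,
                                        linetype = .data$lineage)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (years)", y = "cells",
                  colour = "compartment", linetype = "lineage") +
    ggplot2::theme_minimal()
  if (log10) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot the two feedback signals along a trajectory
#'
#' @param traj An `mdsim_trajectory`.
#' @return A ggplot with `s_p` and `s_a` over time.
#' @export
plot_signals <- function(traj) {
  stopifnot(inherits(traj, "mdsim_trajectory"))
  df <- tidyr::pivot_longer(tibble::as_tibble(traj)[, c("time_years", "s_p",
                                                        "s_a")],
                            c("s_p", "s_a"),
                            names_to = "signal", values_to = "intensity")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_years, .data$intensity,
                                   colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (years)", y = "signal intensity") +
    ggplot2::theme_minimal()
}

#' Stacked bone-marrow composition over time
#'
#' @param traj An `mdsim_trajectory`.
#' @return A ggplot stacked-area chart of bone-marrow percentages.
#' @export
plot_bm_composition <- function(traj) {
  stopifnot(inherits(traj, "mdsim_trajectory"))
  params <- attr(traj, "params")
  lay <- dplyr::filter(state_layout(params), !.data$in_pb)
  df <- tidy(traj) |>
    dplyr::semi_join(dplyr::select(lay, "lineage", compartment = "name"),
                     by = c("lineage", "compartment")) |>
    dplyr::group_by(.data$time_years) |>
    dplyr::mutate(percent = 100 * .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(pool = paste(.data$lineage, .data$compartment, sep = "."))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_years, .data$percent,
                                   fill = .data$pool)) +
    ggplot2::geom_area() +
    ggplot2::labs(x = "time (years)", y = "% of bone-marrow cells") +
    ggplot2::theme_minimal()
}

#' Heatmap of a competition sweep
#'
#' Outcome label per (`a_max_mds`, `p_scale`) grid cell; the takeover
#' boundary runs vertically at the normal stem-cell `a_max`, independent of
#' the proliferation scaling.
#'
#' @param object An `mdsim_sweep` from [sweep_outcomes()].
#' @param ... Unused.
#' @return A ggplot tile plot.
#' @export
autoplot.mdsim_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$a_max_mds,
                                       factor(.data$p_scale),
                                       fill = .data$label)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::labs(x = "MDS stem-cell maximal self-renewal",
                  y = "MDS proliferation scaling", fill = "outcome") +
    ggplot2::theme_minimal()
}
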