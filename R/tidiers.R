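#' Tidy a classified competition outcome
#'
#' @param x An `mdsim_outcome` from [classify_outcome()].
#' @param ... Unused.
#' @return One-row tibble with the label and summary fractions.
#' @export
tidy.mdsim_outcome <- function(x, ...) {
  tibble::tibble(label = x$label,
                 mature_fraction = x$mature_fraction,
                 mds_bm_share = x$mds_bm_share,
                 manifestation_years = x$manifestation_years,
                 horizon_years = x$horizon_years)
}

#' @rdname tidy.mdsim_outcome
#' @export
glance.mdsim_outcome <- function(x, ...) tidy.mdsim_outcome(x, ...)

#' Tidy a trajectory into long format
#'
#' One row per (time, lineage, compartment) with the cell count; convenient
#' for ggplot2 work beyond the provided [autoplot()] methods.
#'
#' @param x An `mdsim_trajectory`.
#' @param ... Unused.
#' @return A long tibble with `time_years`, `lineage`, `compartment`,
#'   `count`, `s_p`, `s_a`.
#' @export
tidy.mdsim_trajectory <- function(x, ...) {
  lay <- state_layout(attr(x, "params"))
  tidyr::pivot_longer(tibble::as_tibble(x), dplyr::all_of(lay$state),
                      names_to = "state", values_to = "count") |>
    dplyr::left_join(dplyr::select(lay, "state", "lineage",
                                   compartment = "name"),
                     by = "state") |>
    dplyr::select("time_days", "time_years", "lineage", "compartment",
                  "count", "s_p", "s_a")
}

#' One-row summary of a simulated trajectory
#'
#' @param x An `mdsim_trajectory`.
#' @param ... Unused.
#' @return One-row tibble: horizon, sample count, solver method, detected
#'   manifestation time, final MDS bone-marrow share.
#' @export
glance.mdsim_trajectory <- function(x, ...) {
  smry <- trajectory_summary(x)
  last <- smry[nrow(smry), ]
  tibble::tibble(
    horizon_years = last$time_years,
    n_samples = nrow(x),
    solver = attr(x, "solver")$method,
    manifestation_years = attr(smry, "manifestation_years"),
    final_mature_rel = last$mature_normal_rel,
    final_mds_bm_share = last$mds_bm_share
  )
}
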