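#' Bone-marrow cellular composition
#'
#' Percentage of bone-marrow cells per compartment. The bone marrow contains
#' every non-peripheral-blood compartment of both lineages (stem and
#' progenitor stages plus precursors and dysplastic precursors); mature
#' peripheral-blood pools are excluded from numerator and denominator.
#'
#' @inheritParams compute_signals
#' @return A tibble with columns `lineage`, `name`, `count`, `percent`;
#'   percentages sum to 100.
#' @export
bm_composition <- function(state, params) {
  y <- as_state_vector(state, params)
  lay <- dplyr::filter(state_layout(params), !.data$in_pb)
  counts <- y[lay$state]
  total <- sum(counts)
  if (total <= 0) stop("empty bone marrow: composition undefined")
  tibble::tibble(lineage = lay$lineage, name = lay$name,
                 count = unname(counts),
                 percent = 100 * unname(counts) / total)
}

#' Apoptotic-cell percentage in the bone marrow
#'
#' Dying cells remain microscopically recognisable as apoptotic for a window
#' `tau` (the feedback parameter `apoptosis_visibility`, default 24 h), so
#' the visible apoptotic pool is the death flux times that window:
#' `A = sum(d_i * c_i * tau)` over bone-marrow compartments with `d_i > 0`.
#' Reported as `100 * A / (BM_total + A)` (the apoptotic pool itself counts
#' toward marrow cellularity by default).
#'
#' @inheritParams compute_signals
#' @param include_apoptotic_in_denominator Count the apoptotic pool in the
#'   denominator (default `TRUE`)?
#' @return Percentage (scalar).
#' @export
apoptotic_fraction <- function(state, params,
                               include_apoptotic_in_denominator = TRUE) {
  y <- as_state_vector(state, params)
  lay <- state_layout(params)
  bm <- !lay$in_pb
  tau <- params$feedback$apoptosis_visibility
  A <- sum(lay$d[bm] * y[lay$state[bm]] * tau)
  denom <- sum(y[lay$state[bm]]) +
    if (include_apoptotic_in_denominator) A else 0
  if (denom <= 0) return(0)
  100 * A / denom
}

#' Primitive (CD34-positive proxy) percentage of the bone marrow
#'
#' The niche-resident compartments of both lineages (by default LT-HSCs,
#' ST-HSCs and MPPs plus their MDS counterparts) serve as the model's proxy
#' for the CD34+ fraction, reported as a percentage of all bone-marrow
#' cells.
#'
#' @inheritParams compute_signals
#' @return Percentage (scalar).
#' @export
primitive_fraction <- function(state, params) {
  y <- as_state_vector(state, params)
  lay <- state_layout(params)
  bm <- !lay$in_pb
  total <- sum(y[lay$state[bm]])
  if (total <= 0) return(0)
  100 * sum(y[lay$state[lay$in_niche]]) / total
}

#' Per-sample summary of a simulated trajectory
#'
#' Tidy per-time-point report of the quantities a disease-course figure
#' would show: normal and MDS mature/bone-marrow counts, both feedback
#' signals, MDS share of the bone marrow, apoptotic and primitive
#' percentages, and mature counts normalised to the healthy baseline.
#'
#' @param traj An `mdsim_trajectory`.
#' @return A tibble with one row per trajectory sample; attribute
#'   `manifestation_years` carries the detected manifestation time (or `NA`).
#' @export
trajectory_summary <- function(traj) {
  stopifnot(inherits(traj, "mdsim_trajectory"))
  params <- attr(traj, "params")
  lay <- state_layout(params)
  states <- as.matrix(traj[, lay$state, drop = FALSE])
  bm <- !lay$in_pb
  tau <- params$feedback$apoptosis_visibility

  bm_tot <- rowSums(states[, bm, drop = FALSE])
  mds_bm <- rowSums(states[, bm & lay$lineage == "mds", drop = FALSE])
  apo <- as.vector(states[, bm, drop = FALSE] %*% (lay$d[bm] * tau))
  prim <- rowSums(states[, lay$in_niche, drop = FALSE])
  mature_n <- rowSums(states[, lay$in_pb & lay$lineage == "normal",
                             drop = FALSE])
  baseline <- attr(traj, "baseline_mature")

  out <- tibble::tibble(
    time_days = traj$time_days,
    time_years = traj$time_years,
    mature_normal = mature_n,
    mature_normal_rel = if (!is.null(baseline) && !is.na(baseline))
      mature_n / baseline else NA_real_,
    bm_total = bm_tot,
    mds_bm_share = ifelse(bm_tot > 0, 100 * mds_bm / bm_tot, NA_real_),
    apoptotic_pct = ifelse(bm_tot + apo > 0, 100 * apo / (bm_tot + apo), 0),
    primitive_pct = ifelse(bm_tot > 0, 100 * prim / bm_tot, NA_real_),
    s_p = traj$s_p,
    s_a = traj$s_a
  )
  attr(out, "manifestation_years") <-
    tryCatch(detect_manifestation(traj), error = function(e) NA_real_)
  out
}
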