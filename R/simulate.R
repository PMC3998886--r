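#' Simulate a disease-course scenario
#'
#' Integrates the feedback-coupled compartment ODEs over a multi-decade
#' horizon. The default initial condition is the healthy steady state with a
#' small number of MDS stem cells seeded (one cell, by default) -- the
#' canonical disease-onset scenario. Internally time is in days; trajectory
#' output also carries years.
#'
#' @param params An `mdsim_model`.
#' @param init Optional initial state (vector or one-row data frame). When
#'   `NULL`, uses `healthy_steady_state(params)` plus `seed_cells` in the
#'   first MDS compartment (if an MDS lineage is present).
#' @param seed_cells MDS stem cells seeded at t = 0 (default 1).
#' @param horizon_years Simulation horizon in years (default 55).
#' @param output_interval_days Output sampling interval (default 30 days).
#' @param solver `"adaptive"` (stiff-capable `deSolve::lsoda`, default) or
#'   `"euler"` (fixed-step oracle; see [euler_oracle()]).
#' @param step Fixed Euler step in days (only for `solver = "euler"`).
#' @param rtol,atol Adaptive-solver tolerances (default `1e-8`).
#'
#' @return A tibble of class `mdsim_trajectory`: columns `time_days`,
#'   `time_years`, one column per `<lineage>.<compartment>`, and the signals
#'   `s_p`, `s_a`. Attributes: `params`, `baseline_mature` (healthy mature
#'   count), `events` (tibble of detected events), `solver`.
#' @export
#' @examples
#' traj <- simulate_model(get_preset("mds_baseline"), horizon_years = 30)
#' detect_manifestation(traj)
simulate_model <- function(params, init = NULL, seed_cells = 1,
                           horizon_years = 55, output_interval_days = 30,
                           solver = c("adaptive", "euler"), step = NULL,
                           rtol = 1e-8, atol = 1e-8) {
  validate_model(params)
  solver <- match.arg(solver)
  stopifnot(horizon_years > 0,
            output_interval_days > 0,
            output_interval_days <= horizon_years * 365)

  baseline <- tryCatch(healthy_steady_state(params), error = function(e) NULL)
  if (is.null(init)) {
    if (is.null(baseline))
      stop("no analytic healthy steady state; supply `init` explicitly")
    init <- baseline
    lay <- state_layout(params)
    mds1 <- which(lay$lineage == "mds")[1]
    if (!is.na(mds1)) init[mds1] <- init[mds1] + seed_cells
  }
  y0 <- as_state_vector(init, params)

  horizon_days <- horizon_years * 365
  times <- unique(c(seq(0, horizon_days, by = output_interval_days),
                    horizon_days))
  cm <- compile_model(params)

  if (solver == "adaptive") {
    sol <- deSolve::lsoda(
      y = y0, times = times,
      func = function(t, y, p) list(rhs_compiled(y, p)),
      parms = cm, rtol = rtol, atol = atol, maxsteps = 50000
    )
    istate <- attr(sol, "istate")
    if (istate[1] < 0)
      stop("ODE solver failed at t = ", max(sol[, 1]), " days")
    mat <- sol[, -1, drop = FALSE]
    solver_info <- list(method = "lsoda", rtol = rtol, atol = atol,
                        steps = istate[3])
  } else {
    if (is.null(step)) step <- min(0.5, output_interval_days)
    mat <- euler_integrate(y0, times, step, cm)
    solver_info <- list(method = "euler", step = step)
  }
  if (any(!is.finite(mat)))
    stop("non-finite state encountered; check parameters or reduce step")
  floor_tol <- -1e-6 * max(1, max(mat))
  if (min(mat) < floor_tol)
    stop("negative cell counts beyond solver tolerance (min = ", min(mat), ")")
  mat[mat < 0] <- 0

  new_trajectory(times, mat, params, baseline, solver_info)
}

# Assemble a trajectory tibble with signals and detected events.
new_trajectory <- function(times, mat, params, baseline, solver_info) {
  cm <- compile_model(params)
  s_p <- 1 / (1 + cm$k_p * rowSums(mat[, cm$in_pb, drop = FALSE]))
  s_a <- 1 / (1 + cm$k_a * rowSums(mat[, cm$in_niche, drop = FALSE]))
  colnames(mat) <- cm$names
  out <- tibble::as_tibble(as.data.frame(mat, optional = TRUE))
  traj <- dplyr::bind_cols(
    tibble::tibble(time_days = times, time_years = times / 365),
    out, tibble::tibble(s_p = s_p, s_a = s_a)
  )
  class(traj) <- c("mdsim_trajectory", class(traj))
  attr(traj, "params") <- params
  attr(traj, "baseline_mature") <- baseline_mature_count(params, baseline)
  attr(traj, "solver") <- solver_info
  ev <- tibble::tibble(name = character(), time_years = numeric())
  tman <- tryCatch(detect_manifestation(traj), error = function(e) NA_real_)
  if (!is.na(tman))
    ev <- tibble::add_row(ev, name = "manifestation", time_years = tman)
  attr(traj, "events") <- ev
  traj
}

baseline_mature_count <- function(params, baseline) {
  if (is.null(baseline)) return(NA_real_)
  lay <- state_layout(params)
  sum(baseline[lay$lineage == "normal" & lay$in_pb])
}

# Fixed-step explicit Euler on the compiled model, sampled at `times`.
euler_integrate <- function(y0, times, step, cm) {
  mat <- matrix(NA_real_, nrow = length(times), ncol = length(y0))
  y <- y0
  t <- times[1]
  mat[1, ] <- y
  for (k in 2:length(times)) {
    target <- times[k]
    while (t < target - 1e-9) {
      h <- min(step, target - t)
      y <- y + h * rhs_compiled(y, cm)
      t <- t + h
      if (any(!is.finite(y)) || min(y) < -0.1 * max(abs(y), 1))
        stop("Euler integration unstable at t = ", round(t, 2),
             " days; use a smaller step")
      y[y < 0] <- 0
    }
    mat[k, ] <- y
  }
  mat
}

#' Fixed-step Euler integration (verification oracle)
#'
#' A deliberately simple first-order integrator used to cross-check the
#' adaptive solver: as `step` shrinks, its solution converges (first order)
#' to the adaptive one. Not intended for production runs.
#'
#' @inheritParams simulate_model
#' @param step Euler step in days. Must satisfy the explicit-Euler stability
#'   bound for the fastest rate in the model: `step < 2 / max(p_max, d)`.
#' @return An `mdsim_trajectory` (see [simulate_model()]).
#' @export
euler_oracle <- function(params, step, init = NULL, seed_cells = 1,
                         horizon_years = 55, output_interval_days = 30) {
  lay <- state_layout(params)
  fastest <- max(lay$p_max, lay$d)
  if (step >= 2 / fastest)
    stop("step ", step, " d too large for fastest rate ", signif(fastest, 3),
         " /d; need step < ", signif(2 / fastest, 3), " d")
  simulate_model(params, init = init, seed_cells = seed_cells,
                 horizon_years = horizon_years,
                 output_interval_days = output_interval_days,
                 solver = "euler", step = step)
}

#' Time of clinical manifestation (cytopenia onset)
#'
#' Manifestation is the first time the normal mature peripheral-blood count
#' falls below `threshold_fraction` of its healthy steady-state value,
#' linearly interpolated between trajectory samples.
#'
#' @param traj An `mdsim_trajectory`.
#' @param threshold_fraction Fraction of the healthy baseline (default 0.5).
#' @param baseline Healthy mature count; defaults to the value stored on the
#'   trajectory.
#' @return Time in years, or `NA` if the threshold is never crossed.
#' @export
detect_manifestation <- function(traj, threshold_fraction = 0.5,
                                 baseline = NULL) {
  stopifnot(inherits(traj, "mdsim_trajectory"),
            threshold_fraction > 0, threshold_fraction < 1)
  params <- attr(traj, "params")
  lay <- state_layout(params)
  mature_cols <- lay$state[lay$lineage == "normal" & lay$in_pb]
  if (length(mature_cols) == 0L)
    stop("trajectory has no normal mature peripheral-blood pool")
  if (is.null(baseline)) baseline <- attr(traj, "baseline_mature")
  if (is.null(baseline) || is.na(baseline))
    stop("healthy baseline mature count unknown; pass `baseline`")
  m <- rowSums(as.matrix(traj[, mature_cols, drop = FALSE]))
  thr <- threshold_fraction * baseline
  below <- which(m < thr)
  if (length(below) == 0L) return(NA_real_)
  i <- below[1]
  if (i == 1L) return(traj$time_years[1])
  # linear interpolation across the crossing interval
  t0 <- traj$time_days[i - 1]; t1 <- traj$time_days[i]
  m0 <- m[i - 1]; m1 <- m[i]
  (t0 + (m0 - thr) / (m0 - m1) * (t1 - t0)) / 365
}
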