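# Shared fixtures. Expensive default-scenario trajectories are computed once
# per test run and memoised here.

baseline_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- get_preset("mds_baseline")
    m
  }
})

baseline_trajectory <- local({
  tr <- NULL
  function() {
    if (is.null(tr))
      tr <<- simulate_model(baseline_model(), horizon_years = 55,
                            output_interval_days = 30)
    tr
  }
})

# random valid single-lineage model for property tests (analytic fixed point
# must exist: stem a_max > 0.5 and strictly above all downstream a_max)
random_normal_model <- function() {
  n_div <- sample(2:5, 1)
  a1 <- runif(1, 0.55, 0.95)
  a <- c(a1, sort(runif(n_div - 1, 0.1, a1 - 0.02), decreasing = TRUE))
  p <- sort(10^runif(n_div, -2, 0))
  rows <- lapply(seq_len(n_div), function(i) {
    compartment_params(paste0("c", i), a_max = a[i], p_max = p[i],
                       in_niche = i <= min(3, n_div))
  })
  rows <- c(rows, list(compartment_params("mature", d = runif(1, 0.5, 3),
                                          divides = FALSE, in_pb = TRUE)))
  model_params(
    list(lineage_params("normal", dplyr::bind_rows(rows))),
    feedback_params(k_p = 10^runif(1, -10, -4), k_a = 10^runif(1, -10, -4),
                    niche_depth = min(3, n_div))
  )
}

# hand-built trajectory object for event-detection tests
synthetic_trajectory <- function(times_years, mature_counts, baseline) {
  params <- get_preset("toy_two_compartment")
  tb <- tibble::tibble(
    time_days = times_years * 365, time_years = times_years,
    normal.stem = 1, normal.mature = mature_counts,
    s_p = 1, s_a = 1
  )
  class(tb) <- c("mdsim_trajectory", class(tb))
  attr(tb, "params") <- params
  attr(tb, "baseline_mature") <- baseline
  tb
}

state_at_year <- function(traj, year) {
  params <- attr(traj, "params")
  i <- which.min(abs(traj$time_years - year))
  vec <- unlist(traj[i, state_layout(params)$state])
  vec
}
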