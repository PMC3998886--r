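test_that("the healthy steady state is stationary over 55 years", {
  m <- get_preset("healthy_default")
  ss <- healthy_steady_state(m)
  traj <- simulate_model(m, init = ss, horizon_years = 55,
                         output_interval_days = 365)
  states <- as.matrix(traj[, state_layout(m)$state])
  drift <- abs(sweep(states, 2, unname(ss), "/") - 1)
  expect_lt(max(drift), 1e-6)
})

test_that("trajectories keep counts nonnegative and signals in (0, 1]", {
  traj <- baseline_trajectory()
  states <- as.matrix(traj[, state_layout(baseline_model())$state])
  expect_true(all(states >= 0))
  expect_true(all(traj$s_p > 0 & traj$s_p <= 1))
  expect_true(all(traj$s_a > 0 & traj$s_a <= 1))
  expect_true(all(diff(traj$time_days) > 0))
})

test_that("the adaptive solution is tolerance-converged", {
  m <- baseline_model()
  t1 <- simulate_model(m, horizon_years = 25, output_interval_days = 90)
  t2 <- simulate_model(m, horizon_years = 25, output_interval_days = 90,
                       rtol = 5e-9, atol = 5e-9)
  s1 <- as.matrix(t1[, state_layout(m)$state])
  s2 <- as.matrix(t2[, state_layout(m)$state])
  rel <- abs(s1 - s2) / (abs(s2) + 1e-6)
  expect_lt(max(rel), 1e-5)
})

test_that("an equal-self-renewal seed neither grows nor declines", {
  m <- modify_mds_clone(get_preset("mds_baseline"), a_max_mds = 0.7)  # tie
  traj <- simulate_model(m, horizon_years = 55, output_interval_days = 365)
  seed_track <- traj$`mds.LT-HSC`
  expect_true(all(abs(seed_track - 1) < 0.01))
})

test_that("the Euler oracle reproduces and converges to the adaptive solution", {
  m <- baseline_model()
  ss <- healthy_steady_state(m)

  # fixed point is constant under Euler at any stable step
  te <- euler_oracle(m, step = 0.25, init = ss, horizon_years = 2,
                     output_interval_days = 73)
  occ <- state_layout(m)$state[ss > 0]
  states <- as.matrix(te[, occ])
  drift <- abs(sweep(states, 2, unname(ss[occ]), "/") - 1)
  expect_lt(max(drift), 1e-9)

  # first-order convergence: halving the step halves the error (Richardson)
  ta <- simulate_model(m, horizon_years = 10, output_interval_days = 365)
  e_for_step <- function(h) {
    te <- euler_oracle(m, step = h, horizon_years = 10,
                       output_interval_days = 365)
    abs(te$normal.mature[11] - ta$normal.mature[11])
  }
  e1 <- e_for_step(0.5)
  e2 <- e_for_step(0.25)
  expect_equal(e1 / e2, 2, tolerance = 0.25)

  # near-exact agreement at a small step over a longer horizon
  te <- euler_oracle(m, step = 0.05, horizon_years = 20,
                     output_interval_days = 730)
  sa <- as.matrix(simulate_model(m, horizon_years = 20,
                                 output_interval_days = 730)[,
                                 state_layout(m)$state])
  se <- as.matrix(te[, state_layout(m)$state])
  rel <- abs(se - sa) / (abs(sa) + 1e-9)
  expect_lt(max(rel[sa > 1]), 0.005)

  expect_error(euler_oracle(m, step = 1), "too large")
})

test_that("manifestation is detected by linear interpolation of the decline", {
  # synthetic piecewise-linear mature track crossing 50% exactly at 3 years
  tr <- synthetic_trajectory(times_years = 0:6,
                             mature_counts = c(100, 90, 70, 40, 30, 20, 10),
                             baseline = 100)
  # crossing of 50 happens between years 2 (70) and 3 (40): at 70-20t = 50
  expect_equal(detect_manifestation(tr, 0.5), 2 + 20 / 30, tolerance = 1e-12)
  tr2 <- synthetic_trajectory(0:6, c(100, 80, 60, 50.0001, 20, 10, 5), 100)
  expect_equal(detect_manifestation(tr2, 0.5), 3, tolerance = 1e-3)

  # healthy-only run never crosses
  m <- get_preset("healthy_default")
  th <- simulate_model(m, horizon_years = 5, output_interval_days = 180)
  expect_true(is.na(detect_manifestation(th)))
})

test_that("scaling gains and counts together leaves the dynamics invariant", {
  m <- get_preset("mds_baseline")
  lambda <- 1e3
  m2 <- m
  m2$feedback$k_p <- m$feedback$k_p * lambda
  m2$feedback$k_a <- m$feedback$k_a * lambda
  t1 <- simulate_model(m, seed_cells = 1, horizon_years = 30,
                       output_interval_days = 180)
  t2 <- simulate_model(m2, seed_cells = 1 / lambda, horizon_years = 30,
                       output_interval_days = 180)
  expect_equal(t2$s_a, t1$s_a, tolerance = 1e-6)
  expect_equal(t2$s_p, t1$s_p, tolerance = 1e-6)
  expect_equal(detect_manifestation(t2), detect_manifestation(t1),
               tolerance = 1e-4)
  i <- nrow(t1)
  c1 <- bm_composition(state_at_year(t1, 30), m)
  c2 <- bm_composition(state_at_year(t2, 30), m2)
  expect_equal(c2$percent, c1$percent, tolerance = 1e-5)
})
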