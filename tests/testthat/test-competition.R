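test_that("self-renewal, not proliferation, decides the simulated outcome", {
  base <- baseline_model()

  # high self-renewal wins even at half the proliferation rate
  slow <- modify_mds_clone(base, a_max_mds = 0.9, p_scale = 0.5)
  t_slow <- simulate_model(slow, horizon_years = 100,
                           output_interval_days = 90)
  expect_equal(classify_outcome(t_slow)$label, "takeover")

  # equal self-renewal cannot take over even at 4x proliferation
  fast <- modify_mds_clone(base, a_max_mds = 0.7, p_scale = 4)
  t_fast <- simulate_model(fast, horizon_years = 100,
                           output_interval_days = 90)
  expect_false(classify_outcome(t_fast)$label == "takeover")

  # healthy-only trajectory: clone absent, trivially no takeover
  mh <- get_preset("healthy_default")
  th <- simulate_model(mh, init = healthy_steady_state(mh),
                       horizon_years = 10, output_interval_days = 365)
  oh <- classify_outcome(th)
  expect_equal(oh$label, "no_takeover")
  expect_equal(oh$mds_bm_share, 0)
})

test_that("sweeps classify deterministically and agree with the predicate", {
  base <- baseline_model()
  g <- sweep_outcomes(base, a_max_mds = c(0.6, 0.66, 0.74, 0.8),
                      p_scale = c(0.5, 2), horizon_years = 100)
  expect_s3_class(g, "mdsim_sweep")
  expect_equal(nrow(g), 8L)
  expect_true(all(is.na(g$error)))

  # outcome is monotone in a_max_mds along every p-slice
  for (ps in unique(g$p_scale)) {
    lab <- g$label[g$p_scale == ps][order(g$a_max_mds[g$p_scale == ps])]
    rank <- match(lab, c("no_takeover", "marginal", "takeover"))
    expect_true(all(diff(rank) >= 0))
  }

  pc <- predicate_concordance(g)
  expect_equal(pc$concordance, 1)
  expect_equal(nrow(pc$discordant), 0L)

  # rerunning gives identical labels (deterministic ODE, fixed order)
  g2 <- sweep_outcomes(base, a_max_mds = c(0.6, 0.66, 0.74, 0.8),
                       p_scale = c(0.5, 2), horizon_years = 100)
  expect_identical(g$label, g2$label)

  # empty grid stays empty, concordance is reported as undefined
  g0 <- sweep_outcomes(base, a_max_mds = numeric(0))
  expect_equal(nrow(g0), 0L)
  expect_true(is.na(predicate_concordance(g0, base)$concordance))
})

test_that("takeover boundary is unchanged in the full-maturation variant", {
  for (preset in c("mds_baseline", "mds_full_maturation")) {
    base <- get_preset(preset)
    below <- modify_mds_clone(base, a_max_mds = 0.65)
    above <- modify_mds_clone(base, a_max_mds = 0.75)
    lb <- classify_outcome(simulate_model(below, horizon_years = 100,
                                          output_interval_days = 90))$label
    la <- classify_outcome(simulate_model(above, horizon_years = 100,
                                          output_interval_days = 90))$label
    expect_equal(lb, "no_takeover", info = preset)
    expect_equal(la, "takeover", info = preset)
  }
})

test_that("higher proliferation accelerates an already-advantaged clone", {
  base <- baseline_model()
  t1 <- simulate_model(modify_mds_clone(base, p_scale = 1),
                       horizon_years = 40, output_interval_days = 30)
  t2 <- simulate_model(modify_mds_clone(base, p_scale = 2),
                       horizon_years = 40, output_interval_days = 30)
  expect_lt(detect_manifestation(t2), detect_manifestation(t1))

  # and latency is monotone in the stem-cell self-renewal advantage
  tms <- vapply(c(0.78, 0.84, 0.9), function(a) {
    detect_manifestation(simulate_model(
      modify_mds_clone(base, a_max_mds = a),
      horizon_years = 80, output_interval_days = 60))
  }, numeric(1))
  expect_true(all(diff(tms) < 0))
})
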