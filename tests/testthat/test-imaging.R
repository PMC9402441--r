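# Trace calibration, log-linear response fits, AUC, volume formulas.

test_that("calibration subtracts background and normalizes by beads", {
  tr <- fluor_trace("c1", time_h = c(0, 1), intensity = c(110, 210),
                    background = c(10, 10), bead_mean = 100)
  cal <- calibrate_trace(tr)
  expect_equal(cal$intensity, c(1.0, 2.0))
  expect_equal(cal$background, c(0, 0))
  expect_equal(cal$bead_mean, 1)
  # idempotent only in the trivial calibrated state
  expect_equal(calibrate_trace(cal)$intensity, cal$intensity)
  tr$bead_mean <- 0
  expect_error(calibrate_trace(tr), "positive")
})

test_that("noiseless exponential traces are recovered exactly in-window", {
  t <- seq(3, 7.5, by = 0.5)
  tr <- fluor_trace("c1", t, exp(1 + 0.5 * t))
  fit <- fit_log_linear(calibrate_trace(tr))
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$slope, 0.5, tolerance = 1e-9)
  expect_equal(fit$r2_fit, 1, tolerance = 1e-12)
  expect_equal(fit$n_points_used, length(t))
})

test_that("constant and degenerate traces fit per contract", {
  t <- seq(3, 7.5, by = 0.5)
  const <- calibrate_trace(fluor_trace("c1", t, rep(4, length(t))))
  fit <- fit_log_linear(const)
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  # a flat trace is fit exactly
  expect_equal(fit$r2_fit, 1)
  # all-background trace: everything dropped as non-positive
  zero <- calibrate_trace(fluor_trace("c2", t, rep(5, length(t)),
                                      background = rep(5, length(t))))
  expect_error(fit_log_linear(zero), "fewer than 3 positive")
})

test_that("three-point fit matches the hand-computed OLS oracle", {
  tr <- calibrate_trace(fluor_trace("c1", c(3, 5, 7), exp(c(0, 1, 1))))
  fit <- fit_log_linear(tr)
  o <- ols_oracle(c(3, 5, 7), c(0, 1, 1))
  expect_equal(fit$slope, o$beta1, tolerance = 1e-12)     # 0.25
  expect_equal(fit$intercept, o$beta0, tolerance = 1e-12) # -7/12
  expect_equal(fit$slope, 0.25, tolerance = 1e-12)
  expect_equal(fit$intercept, -7 / 12, tolerance = 1e-12)
})

test_that("scaling a trace shifts only the intercept, by log of the factor", {
  t <- seq(0, 10, by = 0.5)
  set.seed(41)
  i <- exp(0.8 + 0.4 * t + rnorm(length(t), 0, 0.05))
  f1 <- fit_log_linear(calibrate_trace(fluor_trace("c", t, i)))
  f2 <- fit_log_linear(calibrate_trace(fluor_trace("c", t, 3.7 * i)))
  expect_equal(f2$slope, f1$slope, tolerance = 1e-12)
  expect_equal(f2$intercept, f1$intercept + log(3.7), tolerance = 1e-12)
})

test_that("the analysis window outperforms full-range fits under a lag", {
  cfg <- sim_config(n_cells = 20L, n_genes = 200L, n_qc_fail_cells = 0L,
                    trace_noise_sd = 0, bead_noise_sd = 0, lag_hours = 2,
                    seed = 42)
  traces <- simulate_traces(simulate_truth(cfg), cfg)
  win <- fit_response_profiles(traces, window = c(3, 7.5))
  full <- fit_response_profiles(traces, window = c(0, 10))
  expect_true(all(win$r2_fit > full$r2_fit))
})

test_that("AUC follows the trapezoid rule and is linear", {
  t <- seq(3, 7.5, by = 0.5)
  const <- calibrate_trace(fluor_trace("c", t, rep(1, length(t))))
  expect_equal(auc_trace(const), 4.5, tolerance = 1e-12)
  ramp_i <- (t - 3) / 4.5
  ramp <- calibrate_trace(fluor_trace("c", t, pmax(ramp_i, 1e-12)))
  expect_equal(auc_trace(ramp), 2.25, tolerance = 1e-6)
  half <- calibrate_trace(fluor_trace("c", t, rep(0.5, length(t))))
  expect_equal(auc_trace(half), auc_trace(const) / 2, tolerance = 1e-12)
})

test_that("AUC and slope order a monotone noiseless cohort identically", {
  cfg <- noiseless_config(n_cells = 15L, n_genes = 200L, n_qc_fail_cells = 0L,
                          effect_intercept_pos = 0, intercept_noise_sd = 0,
                          seed = 43)
  tr <- simulate_truth(cfg)
  traces <- lapply(simulate_traces(tr, cfg), calibrate_trace)
  slopes <- fit_response_profiles(traces)$slope
  aucs <- vapply(traces, auc_trace, 0)
  expect_equal(cor(rank(slopes), rank(aucs)), 1)
})

test_that("volume formulas reproduce hand-computed values", {
  v1 <- cell_volume_from_diameters(10, 10, 10)
  expect_equal(v1$value_pl, pi / 6 * 1000 / 1000, tolerance = 1e-9) # 0.5236 pl
  v2 <- cell_volume_from_diameters(8, 10, 12)
  expect_equal(v2$value_pl, v1$value_pl, tolerance = 1e-12)
  v3 <- cell_volume_from_diameters(20, 20, 20)
  expect_equal(v3$value_pl, 8 * v1$value_pl, tolerance = 1e-12)
  expect_error(cell_volume_from_diameters(0, 10, 10), "positive")

  expect_equal(probe_channel_volume(1137.5)$value_pl, 1.0, tolerance = 1e-9)
  expect_equal(probe_channel_volume(0)$value_pl, 0.09, tolerance = 1e-12)
  expect_error(probe_channel_volume(-1), "non-negative")
})

test_that("extracted volume cancels the tip term and flags non-positives", {
  ev <- extracted_volume(500, 1750)
  expect_equal(ev$value_pl, 1.0, tolerance = 1e-12)
  expect_false(ev$flagged)
  eq <- extracted_volume(500, 500)
  expect_equal(eq$value_pl, 0)
  expect_true(eq$flagged)
  expect_warning(neg <- extracted_volume(1750, 500), "negative")
  expect_true(neg$flagged)
  # round trip: invert the area from a volume, recover the volume exactly
  for (v_pl in c(0.2, 1.1, 3.5)) {
    area_after <- (v_pl * 1000) / 0.8 + 500
    expect_equal(extracted_volume(500, area_after)$value_pl, v_pl,
                 tolerance = 1e-9)
  }
})
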