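test_that("z-score uses baseline statistics with the n-1 convention", {
  v <- c(1, 2, 3, rep(2, 17))            # baseline holds {1,2,3}: mu=2, s=1
  tr <- vd_trace(v, fs = 1, baseline_window = c(0, 3))
  z <- zscore(tr)
  expect_equal(z$value[1:3], c(-1, 0, 1))
  expect_equal(z$value[10], 0)

  tr2 <- vd_trace(c(1, 2, 3, 4), fs = 1, baseline_window = c(0, 3))
  z2 <- zscore(tr2)
  expect_equal(z2$value[4], 2)           # x = 4 two sample-SDs above mu

  flat <- vd_trace(rep(5, 20), fs = 1, baseline_window = c(0, 10))
  expect_error(zscore(flat), class = "vasodyn_degenerate_baseline")
})

test_that("z-score is invariant to positive affine transforms", {
  g <- gen_response_trace(baseline = 3, noise_sd = 0.5, onset_true = 12,
                          seed = 8)
  z1 <- zscore(g$trace)
  for (ab in list(c(2, 1), c(0.5, -4), c(10, 100))) {
    scaled <- vd_trace(ab[1] * g$trace$value + ab[2], fs = g$trace$fs,
                       baseline_window = g$trace$baseline_window)
    expect_equal(zscore(scaled)$value, z1$value, tolerance = 1e-10)
  }
})

test_that("trial averaging interpolates onto a 0.1 s grid", {
  t1 <- vd_trace(sin(seq(0, 30, by = 0.05))[-1], fs = 20)
  avg1 <- average_trials(list(t1, t1))
  expect_equal(diff(avg1$time)[1], 0.1)
  expect_equal(max(abs(avg1$sd)), 0)
  oracle <- stats::approx(t1$time, t1$value, xout = avg1$time)$y
  expect_equal(avg1$mean$value, oracle, tolerance = 1e-9)

  up <- vd_trace(rep(1, 100), fs = 10)
  dn <- vd_trace(rep(-1, 100), fs = 10)
  avg2 <- average_trials(list(up, dn))
  expect_true(all(avg2$mean$value == 0))
  expect_equal(avg2$sd[1], sqrt(2))      # n-1 convention on {+1, -1}

  single <- average_trials(list(up))
  expect_true(all(is.na(single$sd)))

  late <- vd_trace(rep(1, 100), fs = 10, t0 = 50, baseline_window = c(50, 55))
  expect_error(average_trials(list(up, late)), class = "vasodyn_out_of_support")
})

test_that("AUC is a trapezoidal integral with window checks", {
  # unit rectangle over [10, 20]
  v <- ifelse(seq(0, 30, by = 0.01)[-1] >= 10 & seq(0, 30, by = 0.01)[-1] <= 20,
              1, 0)
  tr <- vd_trace(v, fs = 100)
  expect_equal(auc(tr, c(10, 20)), 10, tolerance = 0.02)

  # triangle peaking at 2 over [10, 20]: area 10 (trapezoid oracle)
  t <- seq(0, 30, by = 0.01)[-1]
  tri <- pmax(0, 2 * (1 - abs(t - 15) / 5))
  trt <- vd_trace(tri, fs = 100)
  expect_equal(auc(trt, c(10, 20)), 10, tolerance = 1e-5)

  expect_error(auc(vd_trace(rep(1, 200), fs = 10), c(25, 35)),
               class = "vasodyn_out_of_support")

  # additivity over adjacent windows and linearity
  g <- gen_response_trace(noise_sd = 0.5, seed = 3)$trace
  expect_equal(auc(g, c(10, 14)) + auc(g, c(14, 18)), auc(g, c(10, 18)),
               tolerance = 1e-9)
  g2 <- vd_trace(3 * g$value, fs = g$fs, baseline_window = g$baseline_window)
  expect_equal(auc(g2, c(10, 18)), 3 * auc(g, c(10, 18)), tolerance = 1e-9)
})

test_that("blood flow is pi R^2 v with quadratic diameter sensitivity", {
  d <- vd_trace(rep(2, 100), fs = 10, units = "um")
  v <- vd_trace(rep(1, 100), fs = 10, units = "mm/s")
  q <- blood_flow(d, v)
  expect_equal(q$value[1], pi, tolerance = 1e-12)

  d2 <- vd_trace(rep(4, 100), fs = 10, units = "um")
  expect_equal(blood_flow(d2, v)$value[1], 4 * pi, tolerance = 1e-12)

  vneg <- vd_trace(rep(-1, 100), fs = 10, units = "mm/s")
  expect_equal(blood_flow(d, vneg)$value[1], -pi, tolerance = 1e-12)

  dbad <- vd_trace(c(rep(2, 50), 0, rep(2, 49)), fs = 10)
  expect_error(blood_flow(dbad, v), class = "vasodyn_invalid_parameter")

  # first-order identity: %dQ ~ 2 %dD + %dv at 1% perturbations
  q0 <- pi
  q1 <- blood_flow(vd_trace(rep(2 * 1.01, 10), fs = 10, baseline_window = c(0, 0.9)),
                   vd_trace(rep(1.01, 10), fs = 10, baseline_window = c(0, 0.9)))$value[1]
  expect_lt(abs((q1 - q0) / q0 - 0.03), 1e-3)
})

test_that("respiratory rate tracks inter-valley intervals", {
  # valleys every 0.25 s: 4 Hz
  t <- seq(0, 10, by = 0.005)[-1]
  v <- -exp(-((t %% 0.25) - 0.125)^2 / (2 * 0.02^2))
  tr <- vd_trace(v, fs = 200, baseline_window = c(1, 9))
  r <- respiratory_rate(tr)
  expect_equal(mean(r$value), 4, tolerance = 0.01)

  g <- gen_thermocouple(3, deflection_depth = 1, noise_sd = 0.1,
                        duration = 20, fs = 100, seed = 6)
  rg <- respiratory_rate(g$trace)
  expect_lt(abs(mean(rg$value) - 3) / 3, 0.05)

  flat <- vd_trace(rep(0, 2000), fs = 100, baseline_window = c(1, 9))
  expect_error(respiratory_rate(flat), class = "vasodyn_no_rate")
})

test_that("blood-pressure features follow peaks and valleys", {
  g <- gen_bp_waveform(120, 120, 80, fs = 250, duration = 20)
  f <- bp_features(g$trace)
  expect_equal(mean(f$heart_rate$bpm), 120, tolerance = 0.5)
  expect_equal(mean(f$mean_bp$value), 100, tolerance = 0.5)
  expect_error(bp_features(vd_trace(rep(100, 1000), fs = 100,
                                    baseline_window = c(0, 5))),
               class = "vasodyn_no_beats")
})
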