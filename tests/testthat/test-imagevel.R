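test_that("FWHM diameter handles rectangular, Gaussian and flat profiles", {
  rect <- c(rep(0, 20), rep(1, 10), rep(0, 20))
  expect_equal(diameter_fwhm(rect, px_size = 0.5), 5.0, tolerance = 0.03)

  x <- seq_len(101)
  gauss <- exp(-(x - 51)^2 / (2 * 2^2))
  # FWHM of a Gaussian = 2 sqrt(2 ln 2) sigma = 4.7096 px
  expect_equal(diameter_fwhm(gauss, px_size = 1), 2 * sqrt(2 * log(2)) * 2,
               tolerance = 0.05)

  expect_error(diameter_fwhm(rep(1, 50)), class = "vasodyn_no_vessel")
})

test_that("diameter time series recovers constant and oscillating lumens", {
  kc <- gen_kymograph(vessel_diameter = 20, orientation = "transverse",
                      duration = 0.1, line_rate = 1000, px_size = 1,
                      scan_len_px = 64, noise_sd = 0, seed = 1)
  d <- diameter_timeseries(kc$kymo, smoothing_window = 5)
  expect_true(all(abs(d$value - 20) < 1))   # within 1 px

  # 10% sinusoidal dilation at 0.1 Hz, 20 s of slow line scanning
  nl <- 2000
  dia <- 20 * (1 + 0.1 * sin(2 * pi * 0.1 * seq_len(nl) / 100))
  ks <- gen_kymograph(vessel_diameter = dia, orientation = "transverse",
                      duration = 20, line_rate = 100, px_size = 0.5,
                      scan_len_px = 96, noise_sd = 0, seed = 2)
  ds <- diameter_timeseries(ks$kymo, smoothing_window = 10)
  amp <- (max(ds$value) - min(ds$value)) / 2
  expect_lt(abs(amp - 2) / 2, 0.1)

  expect_error(diameter_timeseries(gen_kymograph(seed = 1)$kymo),
               class = "vasodyn_invalid_parameter")  # longitudinal input
})

test_that("lumen area matches the rasterised-disk pixel count", {
  movie <- make_disk_movie(radius = 10)
  res <- lumen_area_timeseries(movie, px_size = 1, frame_rate = 3)
  expect_equal(res$area$value[1], pi * 10^2, tolerance = 0.02)
  expect_equal(res$eq_diameter$value[1], 20, tolerance = 0.01 * 20)

  big <- lumen_area_timeseries(make_disk_movie(radius = 20, size = 64),
                               px_size = 1, frame_rate = 3)
  expect_equal(big$area$value[1] / res$area$value[1], 4, tolerance = 0.02)

  blank <- array(0, c(2, 32, 32))
  expect_error(lumen_area_timeseries(blank), class = "vasodyn_segmentation")
})

test_that("LSPIV recovers synthetic velocities, zero, and sign symmetry", {
  k <- gen_kymograph(velocity_true = 2, line_rate = 2000, px_size = 1,
                     noise_sd = 0.02, seed = 4)
  v <- lspiv_velocity(k$kymo)
  expect_lt(abs(mean(v$velocity) - 2) / 2, 0.05)
  expect_true(all(v$quality >= 0 & v$quality <= 1))

  # static pattern: exactly zero
  k0 <- gen_kymograph(velocity_true = 0, noise_sd = 0, duration = 0.1, seed = 5)
  expect_true(all(lspiv_velocity(k0$kymo)$velocity == 0))

  # time reversal flips the sign, magnitude unchanged
  rev <- vd_kymograph(k$kymo$data[nrow(k$kymo$data):1, ], k$kymo$line_rate,
                      k$kymo$px_size, "longitudinal")
  vr <- lspiv_velocity(rev)
  expect_equal(mean(vr$velocity), -mean(v$velocity), tolerance = 0.02)
})

test_that("streak-angle velocimetry matches geometry and flags isotropy", {
  # 45 degree streaks at 1 um/px and 1 ms line period: 1 mm/s
  k <- gen_kymograph(velocity_true = 1, line_rate = 1000, px_size = 1,
                     noise_sd = 0, duration = 0.1, seed = 6)
  sa <- streak_angle_velocity(k$kymo)
  expect_lt(abs(sa$velocity - 1), 0.03)

  k0 <- gen_kymograph(velocity_true = 0, noise_sd = 0, duration = 0.1, seed = 7)
  expect_lt(abs(streak_angle_velocity(k0$kymo)$velocity), 0.02)

  noise <- vd_kymograph(matrix(rnorm(100 * 64), 100, 64), 1000, 1, "longitudinal")
  expect_error(streak_angle_velocity(noise), class = "vasodyn_no_flow")
})

test_that("LSPIV and streak-angle agree and scale with calibration", {
  for (v_true in c(0.5, 2, 8)) {
    k <- gen_kymograph(velocity_true = v_true, line_rate = 4000, px_size = 1,
                       scan_len_px = 128, noise_sd = 0, duration = 0.2,
                       seed = 10 + v_true)
    v1 <- mean(lspiv_velocity(k$kymo)$velocity)
    v2 <- streak_angle_velocity(k$kymo)$velocity
    expect_lt(abs(v1 - v2) / v_true, 0.10)
  }

  # equivariance: scaling px_size by k scales velocity by k; doubling the
  # line rate doubles velocity for the same image
  k <- gen_kymograph(velocity_true = 2, line_rate = 2000, px_size = 1,
                     noise_sd = 0, duration = 0.2, seed = 20)
  base <- mean(lspiv_velocity(k$kymo)$velocity)
  expect_equal(mean(lspiv_velocity(vd_kymograph(k$kymo$data, 2000, 2,
                                                "longitudinal"))$velocity),
               2 * base, tolerance = 1e-9)
  expect_equal(mean(lspiv_velocity(vd_kymograph(k$kymo$data, 4000, 1,
                                                "longitudinal"))$velocity),
               2 * base, tolerance = 1e-9)
})

test_that("frame realignment recovers constructed shifts", {
  base <- matrix(0, 32, 32)
  base[12:20, 10:22] <- outer(1:9, 1:13)
  movie <- array(0, c(3, 32, 32))
  movie[1, , ] <- base
  movie[2, , ] <- base
  # frame 3 translated by (3, -2)
  shifted <- matrix(0, 32, 32)
  shifted[(12:20) + 3, (10:22) - 2] <- outer(1:9, 1:13)
  movie[3, , ] <- shifted
  res <- realign_frames(movie, roi = c(10, 22, 8, 24))
  expect_equal(res$shifts[2, ], c(0L, 0L))
  expect_equal(res$shifts[3, ], c(-3L, 2L) * -1L)  # shift back by (3, -2)
  expect_error(realign_frames(movie, roi = c(0, 40, 1, 50)),
               class = "vasodyn_invalid_parameter")
})

test_that("dF/F normalises against the baseline-window mean", {
  tr <- vd_trace(rep(10, 100), fs = 10, baseline_window = c(1, 5))
  expect_true(all(dff(tr)$value == 0))

  tr2 <- vd_trace(c(rep(10, 60), rep(15, 40)), fs = 10, baseline_window = c(0, 6))
  expect_equal(dff(tr2)$value[100], 0.5)

  tr0 <- vd_trace(c(rep(0, 60), rep(1, 40)), fs = 10, baseline_window = c(0, 6))
  expect_error(dff(tr0), class = "vasodyn_division")
})
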