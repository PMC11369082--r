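test_that("generators are bit-identical under a fixed seed", {
  a <- gen_response_trace(onset_true = 12, noise_sd = 1, seed = 7)
  b <- gen_response_trace(onset_true = 12, noise_sd = 1, seed = 7)
  expect_identical(a$trace$value, b$trace$value)

  ka <- gen_kymograph(velocity_true = 2, noise_sd = 0.05, seed = 3)
  kb <- gen_kymograph(velocity_true = 2, noise_sd = 0.05, seed = 3)
  expect_identical(ka$kymo$data, kb$kymo$data)

  fa <- gen_fus_ensemble(n_frames = 64, noise_sd = 0.1, seed = 9)
  fb <- gen_fus_ensemble(n_frames = 64, noise_sd = 0.1, seed = 9)
  expect_identical(fa$ens$frames, fb$ens$frames)
})

test_that("response trace honours its construction contract", {
  # null response: the sample mean stays within 3 SE of the baseline level
  g <- gen_response_trace(baseline = 2,
                          response_model = list(amplitude = 0, tau_rise = 0.5,
                                                tau_decay = 10),
                          noise_sd = 0.5, seed = 11)
  se <- 0.5 / sqrt(length(g$trace$value))
  expect_lt(abs(mean(g$trace$value) - 2), 3 * se)

  # noiseless: first sample above baseline is at onset_true +/- one period
  g0 <- gen_response_trace(baseline = 1, onset_true = 12.34, noise_sd = 0,
                           fs = 20, seed = 1)
  t_first <- g0$trace$time[which(g0$trace$value > 1)[1]]
  expect_lt(abs(t_first - 12.34), 1 / 20 + 1e-12)
  expect_true(all(g0$trace$value[g0$trace$time <= 12.34] == 1))

  expect_error(gen_response_trace(fs = -1), class = "vasodyn_invalid_parameter")
  expect_error(gen_response_trace(duration = 5), class = "vasodyn_invalid_parameter")
})

test_that("vasomotion power concentrates at the specified frequency", {
  g <- gen_response_trace(baseline = 10,
                          vasomotion = vasomotion_spec(frequency = 0.1,
                                                       amplitude = 0.05),
                          response_model = list(amplitude = 0, tau_rise = 0.5,
                                                tau_decay = 10),
                          noise_sd = 0.01, duration = 100, fs = 10, seed = 5)
  sp <- stats::spec.pgram(g$trace$value - mean(g$trace$value), plot = FALSE,
                          taper = 0, detrend = TRUE)
  f_peak <- sp$freq[which.max(sp$spec)] * g$trace$fs
  expect_lt(abs(f_peak - 0.1), g$trace$fs / length(g$trace$value) + 1e-9)
})

test_that("kymograph geometry matches the requested velocity", {
  # zero velocity: every column is constant down the time axis
  k0 <- gen_kymograph(velocity_true = 0, noise_sd = 0, duration = 0.1, seed = 1)
  expect_equal(max(apply(k0$kymo$data, 2, function(col) diff(range(col)))), 0)

  # 1 mm/s at 1 um/px and 1 kHz: the pattern advances 1 px per line
  k1 <- gen_kymograph(velocity_true = 1, line_rate = 1000, px_size = 1,
                      noise_sd = 0, duration = 0.1, seed = 2)
  img <- k1$kymo$data
  np <- ncol(img)
  shifted <- img[1, c(np, 1:(np - 1))]       # row 1 moved right by 1 px (circular)
  expect_equal(img[2, ], shifted, tolerance = 1e-10)

  # no RBCs: uniform plasma band
  kp <- gen_kymograph(rbc_density = 0, noise_sd = 0, duration = 0.05, seed = 3)
  expect_equal(diff(range(kp$kymo$data)), 0)

  expect_error(gen_kymograph(velocity_true = 500, line_rate = 1000,
                             px_size = 1, scan_len_px = 64),
               class = "vasodyn_aliasing")
})

test_that("dual-channel pH generator follows the forward sigmoid", {
  cal <- ph_calibration()
  # constant pH, zero noise: constant ratio equal to the forward model
  two <- gen_dual_channel_ph(rep(7.4, 50), calib = cal, r_range_true = 1.2,
                             noise_sd = 0, seed = 1)
  fr <- fluorescence_ratio(two$red, two$green, 20, 30)
  expect_equal(diff(range(fr$value)), 0, tolerance = 1e-12)
  expect_equal(fr$value[1], predict(cal, 7.4, r_range = 1.2), tolerance = 1e-12)

  # acidification brightens H-Ruby: ratio increases when pH steps down
  two2 <- gen_dual_channel_ph(c(rep(7.4, 25), rep(7.25, 25)), calib = cal,
                              noise_sd = 0, seed = 1)
  fr2 <- fluorescence_ratio(two2$red, two2$green, 20, 30)
  expect_gt(fr2$value[50], fr2$value[1])

  expect_error(gen_dual_channel_ph(c(7.4, 2.0)), class = "vasodyn_invalid_parameter")
})

test_that("thermocouple deflection count and intervals track the rate", {
  g <- gen_thermocouple(3, duration = 10, fs = 100, seed = 2)
  expect_lte(abs(length(g$truth$breath_times) - 30), 1)

  # rate step 3 -> 5 Hz at t = 5 s shortens the intervals
  rate <- c(rep(3, 500), rep(5, 500))
  g2 <- gen_thermocouple(rate, duration = 10, fs = 100, seed = 3)
  iv <- diff(g2$truth$breath_times)
  early <- iv[g2$truth$breath_times[-1] < 4.5]
  late <- iv[g2$truth$breath_times[-1] > 5.5]
  expect_gt(mean(early), mean(late))

  # zero-depth deflections leave nothing for rate extraction
  g3 <- gen_thermocouple(3, deflection_depth = 0, duration = 10, seed = 4)
  expect_error(respiratory_rate(g3$trace), class = "vasodyn_no_rate")

  expect_error(gen_thermocouple(5, fs = 20), class = "vasodyn_invalid_parameter")
})

test_that("pressure waveform hits systolic/diastolic at the beat period", {
  g <- gen_bp_waveform(120, 120, 80, fs = 500, duration = 10)
  expect_equal(g$truth$beat_period, 0.5)
  feats <- bp_features(g$trace)
  expect_equal(mean(diff(feats$systolic$time)), 0.5, tolerance = 0.01)
  expect_equal(mean(feats$systolic$value), 120, tolerance = 0.1)
  expect_equal(mean(feats$diastolic$value), 80, tolerance = 0.1)
  expect_equal(mean(feats$mean_bp$value), 100, tolerance = 0.2)

  expect_error(gen_bp_waveform(120, 80, 120), class = "vasodyn_invalid_parameter")
  expect_error(gen_bp_waveform(120, 120, 80, duration = 0),
               class = "vasodyn_empty_trace")
})

test_that("fUS generator places blood at the Doppler frequency and tissue at low rank", {
  expect_equal(doppler_frequency(1, 15), 19.48052, tolerance = 1e-5)

  # tissue_amp 0: all energy in the blood oscillation band
  fe <- gen_fus_ensemble(tissue_amp = 0, blood_components = list(c(1, 1)),
                         n_frames = 256, grid = c(8, 8), noise_sd = 0, seed = 1)
  v <- fe$ens$frames[, 4, 4]
  sp <- stats::spec.pgram(v, plot = FALSE, taper = 0)
  f_peak <- sp$freq[which.max(sp$spec)] * fe$ens$frame_rate
  expect_lt(abs(f_peak - 19.48), 2 * fe$ens$frame_rate / 256)

  # rank-1 tissue, no blood: exactly one dominant singular value
  ft <- gen_fus_ensemble(tissue_amp = 10, tissue_rank = 1,
                         blood_components = list(c(1, 0)),
                         n_frames = 64, grid = c(6, 6), noise_sd = 0, seed = 2)
  d <- svd(matrix(ft$ens$frames, 64, 36))$d
  expect_gt(d[1], 1)
  expect_lt(d[2] / d[1], 1e-10)

  expect_error(gen_fus_ensemble(blood_components = list(c(20, 1)),
                                frame_rate = 500),
               class = "vasodyn_aliasing")
  expect_error(gen_fus_ensemble(n_frames = 1, tissue_rank = 1),
               class = "vasodyn_invalid_parameter")
})
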