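test_that("SVD clutter filter: identity, suppression, Parseval, idempotence", {
  fe <- gen_fus_ensemble(tissue_amp = 100, tissue_rank = 1,
                         blood_components = list(c(1, 1)),
                         n_frames = 256, grid = c(8, 8), noise_sd = 0, seed = 1)
  # n_remove = 0 is the identity
  id <- svd_clutter_filter(fe$ens, 0)
  expect_lt(max(abs(id$frames - fe$ens$frames)) / max(abs(fe$ens$frames)), 1e-10)

  filt <- svd_clutter_filter(fe$ens, 1)
  # tissue-only reference: energy of the pure tissue ensemble
  tis <- gen_fus_ensemble(tissue_amp = 100, tissue_rank = 1,
                          blood_components = list(c(1, 0)),
                          n_frames = 256, grid = c(8, 8), noise_sd = 0, seed = 1)
  blood_only <- fe$ens$frames - tis$ens$frames
  # removed component carries the tissue: residual tissue power < -40 dB
  resid_tissue <- sum((filt$frames - blood_only)^2)
  expect_lt(10 * log10(resid_tissue / sum(tis$ens$frames^2)), -40)
  # blood-band power preserved within 10%
  expect_lt(abs(sum(filt$frames^2) / sum(blood_only^2) - 1), 0.10)

  # Parseval split to < 1e-9 relative
  expect_lt(abs(attr(filt, "energy_input") - attr(filt, "energy_kept") -
                  attr(filt, "energy_removed")) / attr(filt, "energy_input"),
            1e-9)

  # idempotence: reapplying the same clutter projection changes nothing
  twice <- svd_clutter_filter(filt, 1, basis = attr(filt, "clutter_basis"))
  expect_lt(max(abs(twice$frames - filt$frames)) / max(abs(filt$frames)), 1e-10)
  # and when the clutter fully spans the removed subspace, re-estimation too
  tis2 <- svd_clutter_filter(tis$ens, 1)
  tis3 <- svd_clutter_filter(tis2, 1)
  expect_lt(max(abs(tis3$frames - tis2$frames)),
            1e-10 * max(abs(tis$ens$frames)))

  expect_error(svd_clutter_filter(fe$ens, 256), class = "vasodyn_invalid_parameter")
})

test_that("n_remove default scales with ensemble length", {
  expect_identical(default_n_remove(500L), 40L)
  expect_identical(default_n_remove(400L), 40L)
  expect_identical(default_n_remove(200L), 20L)
})

test_that("power Doppler is the slow-time mean square", {
  z <- vd_fus_ensemble(array(0, c(100, 4, 4)), 500, 15)
  pd0 <- power_doppler(z)
  expect_true(all(pd0$pd_map == 0))

  # unit sinusoid with an integer number of periods: PD = 1/2
  n <- 500
  arr <- array(0, c(n, 2, 2))
  arr[, 1, 1] <- sin(2 * pi * 25 * (0:(n - 1)) / 500)   # 25 Hz, 25 full periods
  ens <- vd_fus_ensemble(arr, 500, 15)
  pd <- power_doppler(ens)
  expect_lt(abs(pd$pd_map[1, 1] - 0.5), 1e-6)

  # zero-phase Butterworth smoothing has unit DC gain: mean preserved to 1%
  fe <- gen_fus_ensemble(tissue_amp = 0, blood_components = list(c(1, 1)),
                         n_frames = 2000, grid = c(4, 4), noise_sd = 0.2,
                         seed = 3)
  raw <- power_doppler(fe$ens)
  sm <- power_doppler(fe$ens, smooth_cutoff_hz = 0.4)
  expect_lt(abs(mean(sm$pd_trace$value) / mean(raw$pd_trace$value) - 1), 0.01)
})

test_that("velocity band filters pass/reject by Doppler frequency", {
  slow_c <- gen_fus_ensemble(tissue_amp = 0, blood_components = list(c(1, 1)),
                             n_frames = 512, grid = c(4, 4), noise_sd = 0,
                             seed = 4)   # 1 mm/s ~ 19.5 Hz
  fast_c <- gen_fus_ensemble(tissue_amp = 0, blood_components = list(c(5, 1)),
                             n_frames = 512, grid = c(4, 4), noise_sd = 0,
                             seed = 5)   # 5 mm/s ~ 97 Hz
  e_slow <- sum(slow_c$ens$frames^2)
  e_fast <- sum(fast_c$ens$frames^2)

  sb_slow <- sum(velocity_band_filter(slow_c$ens, "slow")$frames^2)
  fb_slow <- sum(velocity_band_filter(slow_c$ens, "fast")$frames^2)
  expect_gt(sb_slow / e_slow, 0.8)                       # passes the slow band
  expect_lt(10 * log10(fb_slow / e_slow), -20)           # >20 dB down in fast

  sb_fast <- sum(velocity_band_filter(fast_c$ens, "slow")$frames^2)
  fb_fast <- sum(velocity_band_filter(fast_c$ens, "fast")$frames^2)
  expect_gt(fb_fast / e_fast, 0.8)
  expect_lt(10 * log10(sb_fast / e_fast), -20)

  # mm/s <-> Hz mapping: the 0.5-1.5 mm/s <-> 10-30 Hz pairing implies
  # 20 Hz per mm/s; the acoustic mapping gives 19.48, within 3%
  expect_lt(abs(doppler_frequency(1, 15) / 20 - 1), 0.03)
  b <- velocity_band_filter(slow_c$ens, list(mms = c(0.5, 1.5)))
  expect_equal(attr(b, "band_hz"), doppler_frequency(c(0.5, 1.5), 15),
               tolerance = 1e-12)

  expect_error(velocity_band_filter(slow_c$ens, list(hz = c(300, 400))),
               class = "vasodyn_invalid_parameter")
})

test_that("dPD/PD references the 1-10 s baseline", {
  tr <- vd_trace(rep(4, 200), fs = 10, baseline_window = c(1, 10))
  expect_true(all(dpd_response(tr)$value == 0))

  v <- c(rep(2, 100), rep(4, 100))
  tr2 <- vd_trace(v, fs = 10, baseline_window = c(1, 10))
  d <- dpd_response(tr2)
  expect_equal(d$value[200], 100)

  expect_error(dpd_response(vd_trace(rep(1, 50), fs = 10,
                                     baseline_window = c(0, 4)),
                            baseline = c(20, 30)),
               class = "vasodyn_invalid_parameter")
})

test_that("activation maps localise a responsive region", {
  mask <- matrix(FALSE, 8, 8); mask[3:6, 3:6] <- TRUE
  resp <- function(t) 1 + 0.1 * (t > 20 & t < 30)   # +21% power when active
  # steady blood everywhere plus a stimulus-responsive population in the ROI
  base <- gen_fus_ensemble(tissue_amp = 0, blood_components = list(c(2, 1)),
                           n_frames = 40 * 100, frame_rate = 100,
                           grid = c(8, 8), noise_sd = 0.01, seed = 6)
  act <- gen_fus_ensemble(tissue_amp = 0, blood_components = list(c(1, 1)),
                          n_frames = 40 * 100, frame_rate = 100,
                          grid = c(8, 8), noise_sd = 0,
                          blood_mask = mask, response = resp, seed = 7)
  ens <- vd_fus_ensemble(base$ens$frames + act$ens$frames, 100, 15)
  m <- activation_map(ens, stim_times = 20, baseline_offset = c(-9, 0),
                      post_offset = c(2, 8))
  expect_gt(min(m[mask]), 7)           # responsive ROI clearly above
  expect_lt(max(abs(m[!mask])), 2)     # steady background within +/-2%

  expect_error(activation_map(ens, stim_times = 39.9),
               class = "vasodyn_out_of_support")
  expect_error(activation_map(ens, numeric(0)),
               class = "vasodyn_invalid_parameter")
})
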