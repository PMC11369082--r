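# Seeded synthetic generators for every signal the analysis chain consumes.
# Each generator returns its data together with a `truth` list carrying the
# ground-truth parameters (and the seed), so downstream estimators can be
# tested by parameter recovery without any acquired data.

#' Vasomotion specification
#'
#' Spontaneous arteriolar diameter oscillation riding on the baseline; in
#' cortical arterioles it concentrates near 0.1 Hz and is the main nuisance the
#' z-score normalisation targets.
#'
#' @param frequency oscillation frequency, Hz (default 0.1).
#' @param amplitude fractional amplitude relative to baseline (>= 0).
#' @param phase radians, or `"random"` to draw one from the generator seed.
#' @return list of class `vd_vasomotion`.
#' @export
vasomotion_spec <- function(frequency = 0.1, amplitude = 0.02, phase = "random") {
  if (frequency <= 0) vd_stop("invalid_parameter", "vasomotion frequency must be > 0")
  if (amplitude < 0) vd_stop("invalid_parameter", "vasomotion amplitude must be >= 0")
  structure(list(frequency = frequency, amplitude = amplitude, phase = phase),
            class = "vd_vasomotion")
}

#' @keywords internal
vasomotion_wave <- function(spec, t) {
  ph <- if (identical(spec$phase, "random")) stats::runif(1, 0, 2 * pi) else spec$phase
  spec$amplitude * sin(2 * pi * spec$frequency * t + ph)
}

#' Simulate a stimulus-locked response trace
#'
#' Builds `baseline * (1 + vasomotion) + response + noise` on a uniform grid.
#' The response is the gated double-exponential [response_shape()]: exactly
#' zero before `onset_true`, signed amplitude (negative for velocity or GCaMP
#' decreases). The default layout mirrors the study conditions: stimulus at
#' 10 s, 9 s baseline over [1, 10) s.
#'
#' @param baseline resting level, trace units.
#' @param vasomotion a [vasomotion_spec()].
#' @param response_model list with `amplitude`, `tau_rise`, `tau_decay`.
#' @param onset_true response start, seconds from recording start.
#' @param noise_sd additive Gaussian noise SD, trace units.
#' @param duration recording length, seconds.
#' @param fs sampling rate, Hz.
#' @param seed integer RNG seed.
#' @param units unit label for the trace.
#' @return list with `trace` ([vd_trace]) and `truth` (onset, peak amplitude,
#'   model parameters, seed).
#' @examples
#' g <- gen_response_trace(onset_true = 12, seed = 1)
#' g$truth$onset_true
#' @export
gen_response_trace <- function(baseline = 0,
                               vasomotion = vasomotion_spec(amplitude = 0),
                               response_model = list(amplitude = 5,
                                                     tau_rise = 0.5,
                                                     tau_decay = 10),
                               onset_true = 12,
                               noise_sd = 0,
                               duration = 40,
                               fs = 10,
                               seed = 1,
                               units = "z") {
  if (fs <= 0 || duration <= 0)
    vd_stop("invalid_parameter", "fs and duration must be positive")
  if (duration <= 9)
    vd_stop("invalid_parameter", "duration must exceed the 9 s baseline window")
  with_seed(seed, {
    n <- round(duration * fs)
    t <- seq_len(n) / fs - 1 / fs
    vaso <- vasomotion_wave(vasomotion, t)
    resp <- response_shape(t, onset_true, response_model$amplitude,
                           response_model$tau_rise, response_model$tau_decay)
    v <- baseline * (1 + vaso) + resp + stats::rnorm(n, 0, noise_sd)
    trace <- vd_trace(v, fs = fs, units = units, baseline_window = c(1, 10))
    peak_t <- onset_true + response_peak_lag(response_model$tau_rise,
                                             response_model$tau_decay)
    list(trace = trace,
         truth = list(onset_true = onset_true,
                      peak_amp_true = response_model$amplitude,
                      peak_time_true = peak_t,
                      response_model = response_model,
                      baseline = baseline, noise_sd = noise_sd, seed = seed))
  })
}

#' Simulate a line-scan kymograph
#'
#' Renders a space-time image (rows = scan lines / time, columns = position).
#' In `"longitudinal"` orientation, red-blood-cell shadows appear as dark
#' Gaussian streaks (width ~2 px) drifting over a bright plasma background at
#' `velocity_true`; positive velocity moves streaks towards increasing column
#' index. In `"transverse"` orientation the scan crosses the vessel and renders
#' a plasma-bright lumen of width `vessel_diameter` on a dark background.
#'
#' @param velocity_true RBC velocity, mm/s; scalar or one value per line.
#' @param vessel_diameter lumen diameter, um; scalar or per line (transverse).
#' @param duration scan duration, seconds.
#' @param line_rate lines per second, Hz.
#' @param px_size pixel size along the scan, um.
#' @param scan_len_px scan length in pixels.
#' @param rbc_density streaks per 100 um of scan length.
#' @param streak_depth shadow depth, a.u. (plasma level is 1).
#' @param noise_sd additive Gaussian noise SD, a.u.
#' @param orientation `"longitudinal"` or `"transverse"`.
#' @param seed integer RNG seed.
#' @return list with `kymo` (a `vd_kymograph`: matrix plus `line_rate`,
#'   `px_size`, `orientation`) and `truth`.
#' @export
gen_kymograph <- function(velocity_true = 2, vessel_diameter = 20,
                          duration = 1, line_rate = 2000, px_size = 1,
                          scan_len_px = 128, rbc_density = 8,
                          streak_depth = 0.6, noise_sd = 0,
                          orientation = c("longitudinal", "transverse"),
                          seed = 1) {
  orientation <- match.arg(orientation)
  if (line_rate <= 0 || px_size <= 0)
    vd_stop("invalid_parameter", "line_rate and px_size must be positive")
  n_lines <- round(duration * line_rate)
  if (n_lines < 2L) vd_stop("invalid_parameter", "duration too short for line_rate")
  vel <- rep_len(velocity_true, n_lines)
  diam <- rep_len(vessel_diameter, n_lines)
  # displacement per line in px; Nyquist-style guard against streak aliasing
  disp <- vel * 1000 / line_rate / px_size
  if (orientation == "longitudinal" && any(abs(disp) >= scan_len_px / 2))
    vd_stop("aliasing", "displacement per line (%.2f px) exceeds half the scan length",
            max(abs(disp)))
  with_seed(seed, {
    img <- matrix(1, n_lines, scan_len_px)
    if (orientation == "longitudinal") {
      n_streaks <- max(0L, round(rbc_density * scan_len_px * px_size / 100))
      if (n_streaks > 0L) {
        x0 <- stats::runif(n_streaks, 0, scan_len_px)
        path <- cumsum(c(0, disp[-n_lines]))       # px advance of every streak
        cols <- seq_len(scan_len_px) - 0.5
        sigma <- 1                                 # streak half-width ~1 px
        for (k in seq_len(n_streaks)) {
          pos <- (x0[k] + path) %% scan_len_px
          dx <- outer(pos, cols, "-")
          dx <- abs(dx); dx <- pmin(dx, scan_len_px - dx)   # circular distance
          img <- img - streak_depth * exp(-dx^2 / (2 * sigma^2))
        }
      }
    } else {
      cols_um <- (seq_len(scan_len_px) - 0.5) * px_size
      centre <- scan_len_px * px_size / 2
      edge <- px_size / 2                           # soft lumen edge, ~1 px
      for (i in seq_len(n_lines)) {
        r <- abs(cols_um - centre)
        lum <- stats::plogis((diam[i] / 2 - r) / (edge / 2))
        img[i, ] <- 0.1 + 0.9 * lum                # dark background, bright lumen
      }
    }
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd), nrow(img))
    kymo <- vd_kymograph(img, line_rate = line_rate, px_size = px_size,
                         orientation = orientation)
    list(kymo = kymo,
         truth = list(velocity_true = vel, diameter_profile_true = diam,
                      seed = seed))
  })
}

#' Kymograph container
#'
#' @param data intensity matrix, rows = scan lines (time), cols = position.
#' @param line_rate lines per second, Hz.
#' @param px_size pixel size, um.
#' @param orientation `"longitudinal"` or `"transverse"`.
#' @export
vd_kymograph <- function(data, line_rate, px_size,
                         orientation = c("longitudinal", "transverse")) {
  orientation <- match.arg(orientation)
  if (!is.matrix(data) || !length(data))
    vd_stop("invalid_parameter", "kymograph data must be a non-empty matrix")
  if (line_rate <= 0 || px_size <= 0)
    vd_stop("invalid_parameter", "line_rate and px_size must be positive")
  structure(list(data = data, line_rate = line_rate, px_size = px_size,
                 orientation = orientation),
            class = "vd_kymograph")
}

#' @export
print.vd_kymograph <- function(x, ...) {
  cat(sprintf("<vd_kymograph> %d lines x %d px, %g Hz, %g um/px, %s\n",
              nrow(x$data), ncol(x$data), x$line_rate, x$px_size, x$orientation))
  invisible(x)
}

#' Simulate a dual-channel ratiometric pH recording
#'
#' Forward model of the H-Ruby (pH-sensitive, red) / AF488 (pH-insensitive,
#' green) pair: the background-subtracted channel ratio follows the sigmoid
#' \deqn{FR = \alpha_{sys}\left(\frac{R_{Range}}{1 + e^{\alpha_{pH}(pH - pKa)}}
#'   + R_{Cte}\right),}
#' so the ratio rises as the blood acidifies. The green channel is held at a
#' constant plasma level; the red channel carries the pH dependence.
#'
#' @param ph_timecourse pH over time (numeric vector).
#' @param fs sampling rate, Hz.
#' @param calib a [ph_calibration()] model.
#' @param r_range_true per-recording dynamic range (dimensionless).
#' @param green_level pH-insensitive green signal above background, a.u.
#' @param backgrounds c(red, green) channel backgrounds, a.u.
#' @param noise_sd per-channel additive noise SD, a.u.
#' @param seed integer RNG seed.
#' @return list with `red`, `green` ([vd_trace]s) and `truth`.
#' @export
gen_dual_channel_ph <- function(ph_timecourse, fs = 10,
                                calib = ph_calibration(),
                                r_range_true = 1.2,
                                green_level = 100,
                                backgrounds = c(red = 20, green = 30),
                                noise_sd = 0, seed = 1) {
  ph <- as.numeric(ph_timecourse)
  if (any(ph < 3 | ph > 12))
    vd_stop("invalid_parameter", "pH time course outside [3, 12]")
  fr <- ph_forward(ph, calib, r_range = r_range_true)
  with_seed(seed, {
    n <- length(ph)
    green <- green_level + backgrounds[["green"]] + stats::rnorm(n, 0, noise_sd)
    red <- fr * green_level + backgrounds[["red"]] + stats::rnorm(n, 0, noise_sd)
    bw <- default_baseline_window(n / fs)
    list(red = vd_trace(red, fs = fs, units = "a.u.", baseline_window = bw),
         green = vd_trace(green, fs = fs, units = "a.u.", baseline_window = bw),
         truth = list(ph_timecourse_true = ph, r_range_true = r_range_true,
                      backgrounds = backgrounds, calib = calib, seed = seed))
  })
}

#' Simulate a thermocouple respiration trace
#'
#' One downward deflection per inhalation; breath times follow the (possibly
#' time-varying) respiratory rate by phase accumulation, so inter-deflection
#' intervals equal the reciprocal instantaneous rate.
#'
#' @param resp_rate_true breaths per second, Hz; scalar or per sample.
#' @param deflection_depth deflection amplitude, a.u. (positive number; the
#'   deflections go downward).
#' @param noise_sd additive noise SD, a.u.
#' @param duration seconds.
#' @param fs sampling rate, Hz; must be at least 10x the maximum rate.
#' @param seed integer RNG seed.
#' @return list with `trace` ([vd_trace]) and `truth` (breath times, rates).
#' @export
gen_thermocouple <- function(resp_rate_true = 3, deflection_depth = 1,
                             noise_sd = 0, duration = 40, fs = 100, seed = 1) {
  n <- round(duration * fs)
  rate <- rep_len(resp_rate_true, n)
  if (fs < 10 * max(rate))
    vd_stop("invalid_parameter", "fs must be at least 10x the maximum respiratory rate")
  with_seed(seed, {
    t <- seq_len(n) / fs - 1 / fs
    phase <- cumsum(rate) / fs
    breaths <- t[c(FALSE, diff(floor(phase)) > 0)]
    v <- rep(0, n)
    width <- 0.05                                  # inhalation deflection width, s
    for (b in breaths) v <- v - deflection_depth * exp(-(t - b)^2 / (2 * width^2))
    v <- v + stats::rnorm(n, 0, noise_sd)
    list(trace = vd_trace(v, fs = fs, units = "a.u.",
                          baseline_window = default_baseline_window(duration)),
         truth = list(resp_rate_true = rate, breath_times = breaths, seed = seed))
  })
}

#' Simulate an arterial pressure waveform
#'
#' Per-beat maxima equal the systolic pressure, minima the diastolic; the beat
#' period is 60/heart_rate seconds, with an asymmetric (fast upstroke, slower
#' runoff) intra-beat shape.
#'
#' @param heart_rate beats per minute.
#' @param systolic,diastolic pressures, mmHg (systolic > diastolic).
#' @param fs sampling rate, Hz.
#' @param duration seconds (> 0).
#' @param seed integer RNG seed (kept for interface symmetry; the waveform is
#'   deterministic).
#' @return list with `trace` ([vd_trace]) and `truth`.
#' @export
gen_bp_waveform <- function(heart_rate = 500, systolic = 120, diastolic = 80,
                            fs = 100, duration = 40, seed = 1) {
  if (systolic <= diastolic)
    vd_stop("invalid_parameter", "systolic must exceed diastolic")
  if (heart_rate <= 0) vd_stop("invalid_parameter", "heart_rate must be positive")
  if (duration <= 0) vd_stop("empty_trace", "duration must be positive")
  n <- round(duration * fs)
  if (n < 1L) vd_stop("empty_trace", "duration too short for one sample")
  t <- seq_len(n) / fs - 1 / fs
  period <- 60 / heart_rate
  phase <- (t / period) %% 1
  warped <- phase^0.6                              # fast systolic upstroke
  pulse <- 0.5 * (1 - cos(2 * pi * warped))        # in [0, 1], one peak per beat
  v <- diastolic + (systolic - diastolic) * pulse
  list(trace = vd_trace(v, fs = fs, units = "mmHg",
                        baseline_window = c(0, min(duration, 9))),
       truth = list(heart_rate = heart_rate, systolic = systolic,
                    diastolic = diastolic, beat_period = period, seed = seed))
}

#' Axial velocity to slow-time Doppler frequency
#'
#' \eqn{f = 2 v f_0 / c} with speed of sound c = 1540 m/s; at a 15 MHz centre
#' frequency, 1 mm/s maps to about 19.5 Hz.
#'
#' @param v_mms axial velocity, mm/s.
#' @param f0_mhz transmit centre frequency, MHz.
#' @param c_ms speed of sound, m/s.
#' @return Doppler frequency in Hz.
#' @export
doppler_frequency <- function(v_mms, f0_mhz = 15, c_ms = 1540) {
  2 * (v_mms * 1e-3) * (f0_mhz * 1e6) / c_ms
}

#' Functional-ultrasound slow-time ensemble container
#'
#' @param frames 3-D array, slow-time x depth x lateral.
#' @param frame_rate frames per second, Hz.
#' @param center_freq transmit centre frequency, MHz.
#' @export
vd_fus_ensemble <- function(frames, frame_rate = 500, center_freq = 15) {
  if (length(dim(frames)) != 3L || dim(frames)[1] < 2L)
    vd_stop("invalid_parameter", "frames must be a 3-D array with >= 2 frames")
  if (frame_rate <= 0) vd_stop("invalid_parameter", "frame_rate must be positive")
  structure(list(frames = frames, frame_rate = frame_rate,
                 center_freq = center_freq),
            class = "vd_fus_ensemble")
}

#' @export
print.vd_fus_ensemble <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<vd_fus_ensemble> %d frames x %d x %d, %g Hz, f0 %g MHz\n",
              d[1], d[2], d[3], x$frame_rate, x$center_freq))
  invisible(x)
}

#' Simulate a tissue + blood fUS slow-time ensemble
#'
#' The tissue component is a low-rank (exactly `tissue_rank` singular values
#' before noise) space-time term mimicking clutter; each blood component
#' oscillates in slow time at its Doppler frequency \eqn{2 v f_0 / c} with
#' random per-voxel phase, confined to `blood_mask` (default: all voxels).
#'
#' @param tissue_amp clutter amplitude of the leading tissue component, a.u.
#' @param tissue_rank number of tissue singular components.
#' @param blood_components list of `c(velocity_mms, amplitude)` pairs.
#' @param frame_rate slow-time frame rate, Hz.
#' @param center_freq transmit centre frequency, MHz.
#' @param n_frames number of slow-time frames.
#' @param grid c(depth, lateral) voxel grid.
#' @param noise_sd additive Gaussian noise SD.
#' @param blood_mask logical depth x lateral matrix or NULL for all voxels.
#' @param response optional function(t_seconds) -> multiplicative blood
#'   amplitude modulation (for stimulus-responsive ensembles); default none.
#' @param seed integer RNG seed.
#' @return list with `ens` ([vd_fus_ensemble]) and `truth` (axial velocities,
#'   Doppler frequencies, masks, seed).
#' @export
gen_fus_ensemble <- function(tissue_amp = 100, tissue_rank = 1,
                             blood_components = list(c(1, 1)),
                             frame_rate = 500, center_freq = 15,
                             n_frames = 400, grid = c(16, 16),
                             noise_sd = 0, blood_mask = NULL,
                             response = NULL, seed = 1) {
  if (n_frames <= tissue_rank)
    vd_stop("invalid_parameter", "n_frames must exceed tissue_rank")
  fks <- vapply(blood_components, function(bc)
    doppler_frequency(bc[1], center_freq), numeric(1))
  if (any(fks >= frame_rate / 2))
    vd_stop("aliasing", "blood Doppler frequency %.1f Hz at/above Nyquist (%g Hz)",
            max(fks), frame_rate / 2)
  nv <- prod(grid)
  with_seed(seed, {
    t <- seq_len(n_frames) / frame_rate - 1 / frame_rate
    X <- matrix(0, n_frames, nv)
    if (tissue_rank > 0 && tissue_amp > 0) {
      U <- qr.Q(qr(matrix(stats::rnorm(n_frames * tissue_rank), n_frames)))
      V <- qr.Q(qr(matrix(stats::rnorm(nv * tissue_rank), nv)))
      # singular values scaled so tissue_amp is the per-sample RMS amplitude
      amps <- tissue_amp * sqrt(n_frames * nv) * 0.5^(seq_len(tissue_rank) - 1)
      X <- X + U %*% (amps * t(V))
    }
    mask <- if (is.null(blood_mask)) matrix(TRUE, grid[1], grid[2]) else blood_mask
    midx <- which(as.vector(mask))
    mod <- if (is.null(response)) rep(1, n_frames) else response(t)
    for (k in seq_along(blood_components)) {
      amp <- blood_components[[k]][2]
      if (amp == 0) next
      phi <- stats::runif(length(midx), 0, 2 * pi)
      osc <- outer(2 * pi * fks[k] * t, rep(1, length(midx))) +
        outer(rep(1, n_frames), phi)
      X[, midx] <- X[, midx] + (amp * mod) * cos(osc)
    }
    X <- X + matrix(stats::rnorm(length(X), 0, noise_sd), n_frames)
    frames <- array(X, dim = c(n_frames, grid[1], grid[2]))
    list(ens = vd_fus_ensemble(frames, frame_rate, center_freq),
         truth = list(axial_velocities_true = vapply(blood_components, `[`,
                                                     numeric(1), 1),
                      doppler_freqs_true = fks, blood_mask = mask,
                      tissue_rank = tissue_rank, seed = seed))
  })
}
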