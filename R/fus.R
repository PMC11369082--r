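# Functional-ultrasound slow-time processing: SVD clutter rejection, power
# Doppler, axial-velocity band separation, dPD/PD responses, activation maps.

# Casorati matrix (slow-time x voxels) of an ensemble.
#' @keywords internal
casorati <- function(ens) {
  d <- dim(ens$frames)
  matrix(ens$frames, d[1], d[2] * d[3])
}

#' Default number of clutter components to remove
#'
#' 40 components at ensembles of 400 frames or more (the acquisition-scale
#' convention), scaled proportionally (`round(40 * n/400)`) for shorter
#' ensembles.
#'
#' @param n_frames slow-time length.
#' @export
default_n_remove <- function(n_frames) {
  if (n_frames >= 400L) 40L else max(1L, as.integer(round(40 * n_frames / 400)))
}

#' SVD clutter filter
#'
#' Removes the `n_remove` largest singular components of the slow-time
#' Casorati matrix (tissue clutter) and reconstructs the ensemble from the
#' remainder (blood). Energy splits exactly:
#' \eqn{\|input\|^2 = \|kept\|^2 + \|removed\|^2}.
#'
#' @param ens a [vd_fus_ensemble].
#' @param n_remove components removed; default [default_n_remove()].
#' @param center subtract the temporal mean of each voxel first (default
#'   FALSE; when TRUE the mean is counted in the removed energy).
#' @param basis optional temporal clutter basis (orthonormal columns,
#'   slow-time x k) from a previous call's `clutter_basis` attribute; when
#'   supplied, that fixed subspace is projected out instead of re-estimating,
#'   which makes repeated application exactly idempotent.
#' @return filtered [vd_fus_ensemble] with attributes `energy_input`,
#'   `energy_kept`, `energy_removed`, `n_remove`, `clutter_basis`.
#' @export
svd_clutter_filter <- function(ens, n_remove = NULL, center = FALSE,
                               basis = NULL) {
  stopifnot(inherits(ens, "vd_fus_ensemble"))
  X <- casorati(ens)
  n <- nrow(X)
  if (is.null(n_remove)) n_remove <- default_n_remove(n)
  if (n_remove >= n)
    vd_stop("invalid_parameter", "n_remove (%d) must be below the slow-time length (%d)",
            n_remove, n)
  e_in <- sum(X^2)
  if (center) X <- sweep(X, 2, colMeans(X))
  U <- basis
  if (is.null(U) && n_remove > 0L) {
    sv <- svd(X, nu = n_remove, nv = 0)
    U <- sv$u
  }
  if (!is.null(U)) X <- X - U %*% (t(U) %*% X)   # project out clutter subspace
  e_kept <- sum(X^2)
  out <- vd_fus_ensemble(array(X, dim(ens$frames)), ens$frame_rate,
                         ens$center_freq)
  attr(out, "energy_input") <- e_in
  attr(out, "energy_kept") <- e_kept
  attr(out, "energy_removed") <- e_in - e_kept
  attr(out, "n_remove") <- n_remove
  attr(out, "clutter_basis") <- U
  out
}

#' Power Doppler map and time series
#'
#' Per voxel, PD is the mean squared signal over slow time (proportional to
#' cerebral blood volume after clutter filtering). The PD time series is the
#' ROI-mean instantaneous power averaged in sliding windows (default 0.4 s at
#' 50% overlap), optionally smoothed with a zero-phase fifth-order Butterworth
#' low-pass.
#'
#' @param ens a (clutter-filtered) [vd_fus_ensemble].
#' @param roi logical depth x lateral mask, or NULL for the full field.
#' @param window_s sliding-window length, seconds.
#' @param overlap window overlap fraction in [0, 1).
#' @param smooth_cutoff_hz low-pass cutoff for the PD series, or NULL for no
#'   smoothing.
#' @return list of class `vd_pd`: `pd_map` (matrix), `pd_trace` ([vd_trace]).
#' @export
power_doppler <- function(ens, roi = NULL, window_s = 0.4, overlap = 0.5,
                          smooth_cutoff_hz = NULL) {
  stopifnot(inherits(ens, "vd_fus_ensemble"))
  d <- dim(ens$frames)
  if (!d[1]) vd_stop("invalid_parameter", "empty ensemble")
  X <- casorati(ens)
  pd_map <- matrix(colMeans(X^2), d[2], d[3])
  sel <- if (is.null(roi)) seq_len(ncol(X)) else which(as.vector(roi))
  inst <- rowMeans(X[, sel, drop = FALSE]^2)   # instantaneous ROI power
  wlen <- min(d[1], max(1L, round(window_s * ens$frame_rate)))
  step <- max(1L, round(wlen * (1 - overlap)))
  starts <- seq(1L, d[1] - wlen + 1L, by = step)
  pd <- vapply(starts, function(i) mean(inst[i:(i + wlen - 1L)]), numeric(1))
  fs_pd <- ens$frame_rate / step
  if (!is.null(smooth_cutoff_hz)) {
    if (smooth_cutoff_hz >= fs_pd / 2)
      vd_stop("invalid_parameter", "smoothing cutoff at/above the PD Nyquist")
    bf <- signal::butter(5, smooth_cutoff_hz / (fs_pd / 2), type = "low")
    # demean before zero-phase filtering so edge transients act on the
    # fluctuations, not the DC power level
    m <- mean(pd)
    pd <- m + as.numeric(signal::filtfilt(bf, pd - m))
  }
  t0 <- (starts[1] - 1 + (wlen - 1) / 2) / ens$frame_rate
  dur <- length(pd) / fs_pd
  tr <- vd_trace(pd, fs = fs_pd, t0 = t0, units = "PD",
                 baseline_window = c(t0, t0 + min(9, dur * 0.9)))
  structure(list(pd_map = pd_map, pd_trace = tr), class = "vd_pd")
}

#' Convert a Doppler frequency band to axial velocity
#' @param f_hz frequency, Hz.
#' @param f0_mhz centre frequency, MHz.
#' @param c_ms speed of sound, m/s.
#' @return axial velocity, mm/s.
#' @export
doppler_velocity <- function(f_hz, f0_mhz = 15, c_ms = 1540) {
  f_hz * c_ms / (2 * f0_mhz * 1e6) * 1e3
}

#' Separate slow- and fast-flowing blood volume by Doppler band
#'
#' Applies a zero-phase fifth-order Butterworth band-pass (`"slow"`: 10-30 Hz,
#' i.e. 0.5-1.5 mm/s axial velocity at 15 MHz) or high-pass (`"fast"`:
#' > 60 Hz, > 3 mm/s) per voxel along slow time. Custom bands may be given in
#' Hz or mm/s (converted via \eqn{f = 2 v f_0 / c}).
#'
#' @param ens a [vd_fus_ensemble].
#' @param band `"slow"`, `"fast"`, or a list with `hz = c(lo, hi)` or
#'   `mms = c(lo, hi)` (`hi = Inf` for a high-pass).
#' @return filtered [vd_fus_ensemble] with attributes `band_hz` and
#'   `band_mms`.
#' @export
velocity_band_filter <- function(ens, band = "slow") {
  stopifnot(inherits(ens, "vd_fus_ensemble"))
  if (identical(band, "slow")) band <- list(hz = c(10, 30))
  else if (identical(band, "fast")) band <- list(hz = c(60, Inf))
  if (!is.null(band$mms))
    band$hz <- doppler_frequency(band$mms, ens$center_freq)
  hz <- band$hz
  nyq <- ens$frame_rate / 2
  if (hz[1] >= nyq)
    vd_stop("invalid_parameter", "band edge %.1f Hz at/above Nyquist (%g Hz)",
            hz[1], nyq)
  if (is.finite(hz[2]) && hz[2] >= nyq)
    vd_stop("invalid_parameter", "band edge %.1f Hz at/above Nyquist (%g Hz)",
            hz[2], nyq)
  bf <- if (is.finite(hz[2]))
    signal::butter(5, hz / nyq, type = "pass")
  else signal::butter(5, hz[1] / nyq, type = "high")
  X <- casorati(ens)
  Xf <- apply(X, 2, function(col) as.numeric(signal::filtfilt(bf, col)))
  out <- vd_fus_ensemble(array(Xf, dim(ens$frames)), ens$frame_rate,
                         ens$center_freq)
  attr(out, "band_hz") <- hz
  attr(out, "band_mms") <- doppler_velocity(hz, ens$center_freq)
  out
}

#' Fractional power-Doppler response
#'
#' \eqn{100 (PD(t) - PD_{base}) / PD_{base}} with the baseline PD averaged
#' over the baseline window (9 s, from 1 to 10 s, by default).
#'
#' @param pd_trace a [vd_trace] of PD (from [power_doppler()]).
#' @param baseline c(t1, t2), seconds.
#' @return a [vd_trace] in percent.
#' @export
dpd_response <- function(pd_trace, baseline = c(1, 10)) {
  stopifnot(inherits(pd_trace, "vd_trace"))
  sel <- pd_trace$time >= baseline[1] & pd_trace$time < baseline[2]
  if (!any(sel)) vd_stop("invalid_parameter", "baseline window empty")
  p0 <- mean(pd_trace$value[sel])
  if (p0 <= 0) vd_stop("division", "zero baseline power")
  bw <- c(max(baseline[1], pd_trace$time[1]),
          min(baseline[2], max(pd_trace$time)))
  vd_trace(100 * (pd_trace$value - p0) / p0, fs = pd_trace$fs,
           t0 = pd_trace$time[1], units = "dPD/PD (%)", baseline_window = bw)
}

#' Per-voxel stimulus response map
#'
#' For each stimulus repetition, per-voxel PD is averaged over a pre-stimulus
#' baseline and a post-stimulus window; the map is the mean dPD/PD (%) across
#' repetitions.
#'
#' @param ens a (filtered) [vd_fus_ensemble].
#' @param stim_times stimulus onset times, seconds (>= 1 epoch).
#' @param baseline_offset c(t1, t2) relative to each stimulus, seconds.
#' @param post_offset c(t1, t2) relative to each stimulus, seconds.
#' @return matrix (depth x lateral) of mean dPD/PD in percent.
#' @export
activation_map <- function(ens, stim_times, baseline_offset = c(-9, 0),
                           post_offset = c(0, 5)) {
  stopifnot(inherits(ens, "vd_fus_ensemble"))
  if (!length(stim_times)) vd_stop("invalid_parameter", "no stimulus epochs")
  d <- dim(ens$frames)
  t <- seq_len(d[1]) / ens$frame_rate - 1 / ens$frame_rate
  X2 <- casorati(ens)^2
  maps <- lapply(stim_times, function(s) {
    bsel <- t >= s + baseline_offset[1] & t < s + baseline_offset[2]
    psel <- t >= s + post_offset[1] & t < s + post_offset[2]
    if (!any(bsel) || !any(psel) || s + post_offset[2] > max(t) + 1e-9 ||
        s + baseline_offset[1] < t[1] - 1e-9)
      vd_stop("out_of_support", "stimulus epoch at %g s outside the recording", s)
    pb <- colMeans(X2[bsel, , drop = FALSE])
    pp <- colMeans(X2[psel, , drop = FALSE])
    100 * (pp - pb) / pb
  })
  m <- Reduce(`+`, maps) / length(maps)
  matrix(m, d[2], d[3])
}
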