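# Normalisation and summary statistics for physiological time series.

#' Baseline z-score of a trace
#'
#' \eqn{z = (x - \mu_{baseline}) / \sigma_{baseline}} with both statistics
#' taken over the trace's declared baseline window (9 s by convention) and the
#' sample (n - 1) SD. Z-scoring suppresses the contribution of trials and
#' vessels with the largest 0.1 Hz vasomotion fluctuations when averaging.
#'
#' @param trace a [vd_trace].
#' @return a [vd_trace] in z units.
#' @export
zscore <- function(trace) {
  bs <- baseline_stats(trace)
  if (!is.finite(bs$sd) || bs$sd <= 0)
    vd_stop("degenerate_baseline", "baseline SD is zero; cannot z-score")
  vd_trace((trace$value - bs$mean) / bs$sd, fs = trace$fs, t0 = trace$time[1],
           units = "z", baseline_window = trace$baseline_window)
}

#' Average stimulus-aligned trials onto a common grid
#'
#' Trials are linearly interpolated onto a common grid (0.1 s step by default,
#' spanning the overlap of all trials) and averaged pointwise; the per-point
#' sample SD and n are returned alongside.
#'
#' @param trials list of [vd_trace]s sharing units and alignment.
#' @param grid_step interpolation step, seconds.
#' @return list with `mean` ([vd_trace]), `sd` (numeric, NA for n = 1),
#'   `n` (integer) and `time`.
#' @export
average_trials <- function(trials, grid_step = 0.1) {
  if (!length(trials)) vd_stop("invalid_parameter", "need at least one trial")
  stopifnot(all(vapply(trials, inherits, logical(1), "vd_trace")))
  t1 <- max(vapply(trials, function(tr) tr$time[1], numeric(1)))
  t2 <- min(vapply(trials, function(tr) tr$time[length(tr$time)], numeric(1)))
  if (t2 <= t1) vd_stop("out_of_support", "trials have no overlapping time support")
  grid <- seq(t1, t2, by = grid_step)
  mat <- vapply(trials, interp_trace, numeric(length(grid)), at = grid)
  mat <- matrix(mat, nrow = length(grid))
  m <- rowMeans(mat)
  s <- if (length(trials) > 1L) apply(mat, 1, stats::sd) else rep(NA_real_, length(grid))
  bw <- trials[[1]]$baseline_window
  bw <- c(max(bw[1], t1), min(bw[2], t2))
  mean_tr <- vd_trace(m, fs = 1 / grid_step, t0 = grid[1],
                      units = trials[[1]]$units, baseline_window = bw)
  list(mean = mean_tr, sd = s, n = length(trials), time = grid)
}

#' Area under the curve over a time window
#'
#' Trapezoidal integral of (value - reference) over `[t1, t2]`; the reference
#' is zero or the baseline-window mean.
#'
#' @param trace a [vd_trace].
#' @param window c(t1, t2), seconds, within the trace support.
#' @param baseline_ref `"zero"` or `"baseline-mean"`.
#' @return AUC in trace-units x seconds.
#' @export
auc <- function(trace, window, baseline_ref = c("zero", "baseline-mean")) {
  stopifnot(inherits(trace, "vd_trace"))
  baseline_ref <- match.arg(baseline_ref)
  if (window[2] <= window[1])
    vd_stop("invalid_parameter", "AUC window must have positive length")
  rng <- range(trace$time)
  if (window[1] < rng[1] - 1e-9 || window[2] > rng[2] + 1e-9)
    vd_stop("out_of_support", "AUC window outside trace support")
  ref <- if (baseline_ref == "zero") 0 else baseline_stats(trace)$mean
  inside <- trace$time > window[1] & trace$time < window[2]
  tt <- c(window[1], trace$time[inside], window[2])
  vv <- c(interp_trace(trace, window[1]), trace$value[inside],
          interp_trace(trace, window[2])) - ref
  sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2)
}

#' Volumetric blood flow from diameter and velocity
#'
#' \eqn{Q(t) = \pi R(t)^2 v(t)} with R = diameter/2. Inputs sharing a grid are
#' combined directly; otherwise both are interpolated onto the finer grid over
#' their common support.
#'
#' @param diameter [vd_trace] in um (> 0 everywhere).
#' @param velocity [vd_trace] in mm/s.
#' @return a [vd_trace] of flow in um^2.mm/s.
#' @export
blood_flow <- function(diameter, velocity) {
  stopifnot(inherits(diameter, "vd_trace"), inherits(velocity, "vd_trace"))
  bad <- which(diameter$value <= 0)
  if (length(bad))
    vd_stop("invalid_parameter", "non-positive diameter at sample %d", bad[1])
  fs <- max(diameter$fs, velocity$fs)
  t1 <- max(diameter$time[1], velocity$time[1])
  t2 <- min(max(diameter$time), max(velocity$time))
  if (t2 <= t1) vd_stop("out_of_support", "traces have no overlapping support")
  grid <- seq(t1, t2, by = 1 / fs)
  d <- interp_trace(diameter, grid)
  v <- interp_trace(velocity, grid)
  bw <- c(max(diameter$baseline_window[1], t1),
          min(diameter$baseline_window[2], t2))
  if (bw[2] <= bw[1]) bw <- c(t1, t1 + min(9, (t2 - t1) * 0.9))
  vd_trace(pi * (d / 2)^2 * v, fs = fs, t0 = grid[1], units = "um^2.mm/s",
           baseline_window = bw)
}

#' Respiratory rate from a thermocouple trace
#'
#' Inhalations register as downward deflections; valleys are detected with
#' prominence and minimum-interval guards, the instantaneous rate is the
#' reciprocal inter-valley interval (assigned at the later valley), and the
#' rate is linearly resampled onto the trace grid.
#'
#' @param thermo a [vd_trace].
#' @param min_prominence valley prominence threshold, a.u. (default 20% of the
#'   signal range).
#' @param min_interval minimum inter-valley interval, seconds (default 0.08).
#' @return a [vd_trace] of rate in Hz (supported between first and last breath).
#' @export
respiratory_rate <- function(thermo, min_prominence = NULL, min_interval = 0.08) {
  stopifnot(inherits(thermo, "vd_trace"))
  # light running-mean smoothing (~30 ms) suppresses photon/sensor noise
  # without broadening the ~50 ms inhalation deflections
  w <- max(1L, round(0.03 * thermo$fs))
  x <- if (w > 1L) stats::filter(thermo$value, rep(1 / w, w), sides = 2) else thermo$value
  x <- as.numeric(x)
  x[is.na(x)] <- thermo$value[is.na(x)]
  if (is.null(min_prominence)) min_prominence <- 0.2 * diff(range(x))
  if (min_prominence <= 0)
    vd_stop("no_rate", "flat thermocouple trace; no breaths detectable")
  vi <- find_valleys(x, min_prominence = min_prominence,
                     min_distance = max(1L, round(min_interval * thermo$fs)))
  if (length(vi) < 2L)
    vd_stop("no_rate", "fewer than 2 inhalation deflections detected")
  vt <- thermo$time[vi]
  rate <- 1 / diff(vt)
  at <- vt[-1]
  grid <- thermo$time[thermo$time >= at[1] & thermo$time <= at[length(at)]]
  if (length(grid) < 2L) grid <- at
  r <- stats::approx(at, rate, xout = grid, rule = 2)$y
  bw <- c(grid[1], min(thermo$baseline_window[2], grid[length(grid)]))
  if (bw[2] <= bw[1]) bw <- range(grid)
  vd_trace(r, fs = thermo$fs, t0 = grid[1], units = "Hz", baseline_window = bw)
}

#' Beat-wise arterial pressure features
#'
#' Peaks give systolic, valleys diastolic pressure; the mean pressure is the
#' average of each valley and the consecutive peak; heart rate is 60 over the
#' inter-peak interval, in beats per minute.
#'
#' @param bp a [vd_trace] in mmHg.
#' @param min_prominence peak prominence threshold (default 20% of range).
#' @param min_interval minimum inter-beat interval, seconds (default 0.1).
#' @return list of data.frames: `systolic`, `diastolic`, `mean_bp` (time,
#'   value) and `heart_rate` (time, bpm).
#' @export
bp_features <- function(bp, min_prominence = NULL, min_interval = 0.1) {
  stopifnot(inherits(bp, "vd_trace"))
  if (is.null(min_prominence)) min_prominence <- 0.2 * diff(range(bp$value))
  if (min_prominence <= 0) vd_stop("no_beats", "constant pressure trace; no beats")
  dmin <- max(1L, round(min_interval * bp$fs))
  pi_ <- find_peaks(bp$value, min_prominence, dmin)
  vi <- find_valleys(bp$value, min_prominence, dmin)
  if (length(pi_) < 2L) vd_stop("no_beats", "fewer than 2 systolic peaks detected")
  # pair each valley with the next peak
  mean_t <- c(); mean_v <- c()
  for (v in vi) {
    nxt <- pi_[pi_ > v]
    if (length(nxt)) {
      p <- nxt[1]
      mean_t <- c(mean_t, (bp$time[v] + bp$time[p]) / 2)
      mean_v <- c(mean_v, (bp$value[v] + bp$value[p]) / 2)
    }
  }
  hr_t <- bp$time[pi_[-1]]
  hr <- 60 / diff(bp$time[pi_])
  list(systolic = data.frame(time = bp$time[pi_], value = bp$value[pi_]),
       diastolic = data.frame(time = bp$time[vi], value = bp$value[vi]),
       mean_bp = data.frame(time = mean_t, value = mean_v),
       heart_rate = data.frame(time = hr_t, bpm = hr))
}
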