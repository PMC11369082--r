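#' Uniformly sampled physiological time series
#'
#' A `vd_trace` couples a uniformly sampled signal with its sampling rate,
#' units, and a declared baseline window. The baseline window is the reference
#' period used throughout the package for z-scoring, \eqn{\Delta F/F}, and the
#' per-recording pH range; the default convention places the stimulus at 10 s
#' and the baseline over [1, 10) s (a 9 s baseline).
#'
#' @param value numeric vector of samples.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample, seconds (default 0).
#' @param units character unit label (e.g. `"um"`, `"z"`, `"mmHg"`).
#' @param baseline_window two-element numeric, baseline `[t1, t2)` in seconds;
#'   must lie within the time support.
#' @return An object of class `vd_trace`: a list with elements `time`, `value`,
#'   `fs`, `units`, `baseline_window`.
#' @examples
#' tr <- vd_trace(sin(seq(0, 30, by = 0.1))[-1], fs = 10)
#' print(tr)
#' @export
vd_trace <- function(value, fs, t0 = 0, units = "a.u.",
                     baseline_window = c(1, 10)) {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    vd_stop("invalid_parameter", "fs must be a positive number")
  value <- as.numeric(value)
  if (!length(value)) vd_stop("empty_trace", "trace has no samples")
  time <- t0 + seq_along(value) / fs - 1 / fs
  bw <- as.numeric(baseline_window)
  if (length(bw) != 2L || !all(is.finite(bw)) || bw[2] <= bw[1])
    vd_stop("invalid_parameter", "baseline_window must be (t1, t2) with t2 > t1")
  if (bw[1] < time[1] - 1e-9 || bw[2] > time[length(time)] + 1 / fs + 1e-9)
    vd_stop("invalid_parameter", "baseline_window outside the trace support")
  structure(list(time = time, value = value, fs = fs, units = units,
                 baseline_window = bw),
            class = "vd_trace")
}

#' @export
print.vd_trace <- function(x, ...) {
  cat(sprintf("<vd_trace> %d samples @ %g Hz [%s], t = %.3f..%.3f s, baseline [%g, %g) s\n",
              length(x$value), x$fs, x$units, x$time[1], x$time[length(x$time)],
              x$baseline_window[1], x$baseline_window[2]))
  invisible(x)
}

#' @export
as.data.frame.vd_trace <- function(x, ...) {
  data.frame(time_s = x$time, value = x$value)
}

#' @export
plot.vd_trace <- function(x, ..., xlab = "time (s)", ylab = x$units, type = "l") {
  graphics::plot(x$time, x$value, type = type, xlab = xlab, ylab = ylab, ...)
  graphics::abline(v = x$baseline_window, lty = 3, col = "grey50")
  invisible(x)
}

# Default baseline window clamped to a recording of given duration:
# the [1, 10) s convention where it fits, a proportional window otherwise.
#' @keywords internal
default_baseline_window <- function(duration) {
  if (duration > 10.5) c(1, 10) else c(duration * 0.05, duration * 0.6)
}

# Logical index of samples in the (half-open) baseline window.
#' @keywords internal
baseline_idx <- function(trace) {
  trace$time >= trace$baseline_window[1] - 1e-9 &
    trace$time < trace$baseline_window[2] - 1e-9
}

#' Baseline mean and SD of a trace
#'
#' Sample statistics (n - 1 SD convention) over the declared baseline window.
#' @param trace a [vd_trace].
#' @return named list `mean`, `sd`, `n`.
#' @export
baseline_stats <- function(trace) {
  stopifnot(inherits(trace, "vd_trace"))
  v <- trace$value[baseline_idx(trace)]
  if (length(v) < 2L)
    vd_stop("degenerate_baseline", "baseline window holds fewer than 2 samples")
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}

# Linear interpolation of a trace onto new time points; errors outside support.
#' @keywords internal
interp_trace <- function(trace, at) {
  rng <- range(trace$time)
  if (any(at < rng[1] - 1e-9 | at > rng[2] + 1e-9))
    vd_stop("out_of_support", "interpolation time outside trace support")
  stats::approx(trace$time, trace$value, xout = at, rule = 1)$y
}
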