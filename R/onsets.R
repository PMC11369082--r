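# Response-model fitting and onset extraction.
#
# Onsets are defined by the fit rule -- the time at which the fitted curve
# first reaches 10% of its baseline-to-peak deviation -- or by a sustained
# 10%-over-baseline crossing of the measured trace.

#' Fit the canonical response model to a (z-scored) trace
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `b0 + response_shape(t, stim_time + latency, A, tau_r, tau_d)` with a
#' deterministic multi-start grid over latency and rise time; the amplitude is
#' initialised from the post-stimulus extremum. The best converged start wins,
#' ties broken by lower residual then earlier latency. Decreasing responses
#' (velocity drops, GCaMP/pH dips) are handled through the sign of the fitted
#' amplitude; the data are never pre-flipped.
#'
#' @param trace a [vd_trace], z-scored or baseline-referenced.
#' @param stim_time stimulus start, seconds (default 10).
#' @param init_latency deterministic latency starts, seconds after stimulus.
#' @param init_tau_rise rise-time starts, seconds.
#' @param init_tau_decay decay-time start, seconds.
#' @param significance_z amplitude below which (in |z|) the fit is flagged as
#'   no-response (default 2).
#' @return object of class `vd_fit`: fitted `params` (b0, latency, amplitude,
#'   tau_rise, tau_decay), `onset` (absolute response start, s), `peak_value`
#'   (baseline-to-peak deviation), `peak_time` (s), `residual_rms`,
#'   `converged`, `no_response`, plus the stimulus time and data.
#' @examples
#' g <- gen_response_trace(onset_true = 12, noise_sd = 0.5, seed = 2)
#' f <- fit_response(zscore(g$trace))
#' coef(f)
#' @export
fit_response <- function(trace, stim_time = 10,
                         init_latency = c(1, 3, 5, 8),
                         init_tau_rise = c(0.5, 1, 2),
                         init_tau_decay = 10,
                         significance_z = 2) {
  stopifnot(inherits(trace, "vd_trace"))
  t <- trace$time; y <- trace$value
  if (max(t) <= stim_time)
    vd_stop("invalid_parameter", "trace ends before the stimulus")
  b0_init <- baseline_stats(trace)$mean
  post <- y[t >= stim_time] - b0_init
  a_init <- post[which.max(abs(post))]
  if (!is.finite(a_init) || a_init == 0) a_init <- 1
  fn <- function(p) {
    y - (p[1] + response_shape(t, stim_time + p[2], p[3], exp(p[4]), exp(p[5])))
  }
  lower <- c(-Inf, 0, -Inf, log(0.05), log(0.5))
  upper <- c(Inf, max(t) - stim_time, Inf, log(20), log(120))
  best <- NULL
  for (lat in init_latency) for (tr in init_tau_rise) {
    p0 <- c(b0_init, lat, a_init, log(tr), log(init_tau_decay))
    res <- tryCatch(
      minpack.lm::nls.lm(p0, lower = lower, upper = upper, fn = fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(res) || !res$info %in% 1:4) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && res$par[2] < best$par[2])) {
      best <- list(par = res$par, rss = rss)
    }
  }
  if (is.null(best))
    vd_stop("non_convergence", "no start of the response fit converged")
  p <- best$par
  params <- c(b0 = p[1], latency = p[2], amplitude = p[3],
              tau_rise = exp(p[4]), tau_decay = exp(p[5]))
  onset <- stim_time + params[["latency"]]
  peak_time <- onset + response_peak_lag(params[["tau_rise"]],
                                         params[["tau_decay"]])
  rms <- sqrt(best$rss / length(y))
  structure(list(model_name = "gated double-exponential",
                 params = params,
                 onset = onset,
                 peak_value = params[["amplitude"]],
                 peak_time = peak_time,
                 residual_rms = rms,
                 converged = rms < stats::sd(y),
                 no_response = abs(params[["amplitude"]]) < significance_z,
                 stim_time = stim_time,
                 trace = trace),
            class = "vd_fit")
}

#' @export
print.vd_fit <- function(x, ...) {
  cat(sprintf("<vd_fit> %s%s\n", x$model_name,
              if (x$no_response) " [no significant response]" else ""))
  cat(sprintf("  onset %.3f s, peak %.3f at %.3f s, residual RMS %.4g\n",
              x$onset, x$peak_value, x$peak_time, x$residual_rms))
  print(round(x$params, 4))
  invisible(x)
}

#' @export
coef.vd_fit <- function(object, ...) object$params

#' @export
predict.vd_fit <- function(object, times = object$trace$time, ...) {
  p <- object$params
  p[["b0"]] + response_shape(times, object$onset, p[["amplitude"]],
                             p[["tau_rise"]], p[["tau_decay"]])
}

#' @export
residuals.vd_fit <- function(object, ...) {
  object$trace$value - predict(object)
}

#' @export
summary.vd_fit <- function(object, ...) {
  on <- tryCatch(onset_from_fit(object), vasodyn_error = function(e) NULL)
  cat(sprintf("Response fit (%s): converged=%s, no_response=%s\n",
              object$model_name, object$converged, object$no_response))
  print(round(object$params, 4))
  if (!is.null(on))
    cat(sprintf("10%%-of-peak onset: %.3f s after stimulus\n", on$onset_time))
  invisible(object)
}

#' @export
plot.vd_fit <- function(x, ...) {
  plot(x$trace, ...)
  graphics::lines(x$trace$time, predict(x), col = "red", lwd = 2)
  graphics::abline(v = x$stim_time, lty = 2)
  invisible(x)
}

#' Onset by the 10%-of-peak-of-the-fit rule
#'
#' The earliest time at or after the stimulus where the fitted curve's
#' deviation from its baseline level reaches `fraction` of the baseline-to-peak
#' deviation. Sign-aware: works identically for decreasing responses.
#'
#' @param fit a `vd_fit` from [fit_response()].
#' @param fraction threshold fraction of the peak deviation (default 0.10).
#' @return list of class `vd_onset`: `onset_time` (seconds from stimulus
#'   start), `onset_abs` (absolute seconds), `rule`, `fraction`.
#' @export
onset_from_fit <- function(fit, fraction = 0.10) {
  stopifnot(inherits(fit, "vd_fit"))
  if (!fit$converged) vd_stop("non_convergence", "fit did not converge")
  A <- fit$peak_value
  if (A == 0) vd_stop("no_response", "zero fitted amplitude")
  if (fraction >= 1) {
    tcross <- fit$peak_time
  } else {
    dev <- function(t) abs(predict(fit, t) - fit$params[["b0"]]) -
      fraction * abs(A)
    if (dev(fit$peak_time) < 0)
      vd_stop("no_crossing", "fitted curve never reaches the threshold")
    tcross <- stats::uniroot(dev, c(fit$stim_time, fit$peak_time),
                             tol = 1e-9)$root
  }
  structure(list(onset_time = tcross - fit$stim_time, onset_abs = tcross,
                 rule = "fit-10%-of-peak", fraction = fraction),
            class = "vd_onset")
}

#' @export
print.vd_onset <- function(x, ...) {
  cat(sprintf("<vd_onset> %.3f s after stimulus (%s, fraction %g)\n",
              x$onset_time, x$rule, x$fraction))
  invisible(x)
}

#' Onset by sustained crossing of a baseline-referenced threshold
#'
#' For raw-unit traces the threshold is `baseline_mean * (1 +/- fraction)`;
#' for z-scored (or otherwise baseline-referenced) traces it is `fraction`
#' times the post-stimulus peak deviation. The crossing must be sustained for
#' at least `sustain` seconds, rejecting transient vasomotion excursions.
#'
#' @param trace a [vd_trace].
#' @param stim_time stimulus start, seconds.
#' @param fraction threshold fraction (default 0.10).
#' @param direction `"above"` or `"below"` the baseline.
#' @param mode `"relative"` (threshold = baseline*(1 +/- fraction), raw units)
#'   or `"peak"` (threshold = fraction x peak deviation, for z traces).
#' @param sustain minimum time above threshold, seconds (default 0.5).
#' @return a `vd_onset` (see [onset_from_fit()]).
#' @export
onset_above_baseline <- function(trace, stim_time = 10, fraction = 0.10,
                                 direction = c("above", "below"),
                                 mode = c("relative", "peak"),
                                 sustain = 0.5) {
  stopifnot(inherits(trace, "vd_trace"))
  direction <- match.arg(direction)
  mode <- match.arg(mode)
  mu <- baseline_stats(trace)$mean
  post <- trace$time >= stim_time
  if (mode == "relative") {
    thr <- mu * (1 + if (direction == "above") fraction else -fraction)
    crossed <- if (direction == "above") trace$value >= thr else trace$value <= thr
  } else {
    dev <- trace$value - mu
    pk <- if (direction == "above") max(dev[post]) else min(dev[post])
    if ((direction == "above" && pk <= 0) || (direction == "below" && pk >= 0))
      vd_stop("no_crossing", "no post-stimulus deviation in the requested direction")
    crossed <- if (direction == "above") dev >= fraction * pk else dev <= fraction * pk
  }
  crossed <- crossed & post
  need <- max(1L, round(sustain * trace$fs))
  r <- rle(crossed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= need)
  if (!length(ok))
    vd_stop("no_crossing", "no sustained crossing of the baseline threshold")
  tcross <- trace$time[starts[ok[1]]]
  structure(list(onset_time = tcross - stim_time, onset_abs = tcross,
                 rule = sprintf("10%%-over-baseline (%s)", direction),
                 fraction = fraction),
            class = "vd_onset")
}
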