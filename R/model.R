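#' Gated double-exponential response shape
#'
#' The canonical response family used by both the synthetic generators and the
#' onset fitter. The shape is exactly zero before the onset and, for
#' \eqn{s = t - t_0 \ge 0}, follows
#' \deqn{h(s) = (1 - e^{-s/\tau_r})\, e^{-s/\tau_d},}
#' normalised to unit peak, scaled by a signed amplitude. Negative amplitudes
#' represent decreasing responses (velocity drops, GCaMP/pH dips). The peak sits
#' at the closed-form lag \eqn{s^\ast = \tau_r \log(1 + \tau_d/\tau_r)}.
#'
#' @param t time, seconds (vector).
#' @param onset response start time \eqn{t_0}, seconds.
#' @param amplitude signed peak amplitude, trace units.
#' @param tau_rise rise time constant, seconds (> 0).
#' @param tau_decay decay time constant, seconds (> 0).
#' @return numeric vector, the response evaluated at `t`.
#' @seealso [fit_response()], [gen_response_trace()]
#' @export
response_shape <- function(t, onset, amplitude, tau_rise, tau_decay) {
  if (tau_rise <= 0 || tau_decay <= 0)
    vd_stop("invalid_parameter", "tau_rise and tau_decay must be positive")
  s <- t - onset
  h <- numeric(length(s))
  pos <- s > 0
  sp <- s[pos]
  h[pos] <- (1 - exp(-sp / tau_rise)) * exp(-sp / tau_decay)
  amplitude * h / response_peak_height(tau_rise, tau_decay)
}

# Unnormalised peak height and its closed-form lag after onset.
#' @keywords internal
response_peak_lag <- function(tau_rise, tau_decay) {
  tau_rise * log(1 + tau_decay / tau_rise)
}

#' @keywords internal
response_peak_height <- function(tau_rise, tau_decay) {
  s <- response_peak_lag(tau_rise, tau_decay)
  (1 - exp(-s / tau_rise)) * exp(-s / tau_decay)
}
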