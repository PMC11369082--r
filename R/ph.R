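# Ratiometric H-Ruby/AF488 intravascular pH quantification:
# channel ratio -> sigmoid calibration -> per-recording range -> inversion.

#' pH-ratio sigmoid calibration model
#'
#' Parameters of the FR-vs-pH sigmoid
#' \deqn{FR = \alpha_{sys}\left(\frac{R_{Range}}{1+e^{\alpha_{pH}(pH-pKa)}} +
#' R_{Cte}\right).}
#' `alpha_system` is a fixed instrument constant (relative red/green channel
#' sensitivity), never re-fit per recording; `R_Cte` is the pH-insensitive
#' floor (green-dye bleed-through into the red channel); `r_range` is the
#' dynamic range of the calibration preparation and is re-derived per
#' recording with [r_range_from_baseline()]. Defaults are the plasma
#' calibration coefficients used throughout the package examples.
#'
#' @param alpha_ph sigmoid slope, 1/pH (> 0).
#' @param pka inflection point, pH units.
#' @param r_cte pH-insensitive offset (>= 0).
#' @param alpha_system instrument constant (> 0; default 1).
#' @param r_range calibration-table dynamic range (default 1).
#' @param r_squared,fit_cov optional fit diagnostics.
#' @return object of class `ph_calibration`.
#' @export
ph_calibration <- function(alpha_ph = 2.64, pka = 7.47, r_cte = 0.32,
                           alpha_system = 1, r_range = 1,
                           r_squared = NA_real_, fit_cov = NULL) {
  if (alpha_system <= 0 || alpha_ph <= 0)
    vd_stop("invalid_parameter", "alpha_system and alpha_ph must be positive")
  if (pka <= 4 || pka >= 11)
    vd_stop("invalid_parameter", "pKa outside the plausible range (4, 11)")
  if (r_cte < 0) vd_stop("invalid_parameter", "R_Cte must be >= 0")
  structure(list(alpha_ph = alpha_ph, pka = pka, r_cte = r_cte,
                 alpha_system = alpha_system, r_range = r_range,
                 r_squared = r_squared, fit_cov = fit_cov),
            class = "ph_calibration")
}

#' @export
print.ph_calibration <- function(x, ...) {
  cat(sprintf("<ph_calibration> alpha_pH=%.3f, pKa=%.3f, R_Cte=%.3f, alpha_system=%g, R_Range=%.4g",
              x$alpha_ph, x$pka, x$r_cte, x$alpha_system, x$r_range))
  if (is.finite(x$r_squared)) cat(sprintf(", R2=%.5f", x$r_squared))
  cat("\n")
  invisible(x)
}

#' @export
coef.ph_calibration <- function(object, ...) {
  c(alpha_ph = object$alpha_ph, pka = object$pka, r_cte = object$r_cte,
    alpha_system = object$alpha_system, r_range = object$r_range)
}

# Forward sigmoid: pH -> FR.
#' @keywords internal
ph_forward <- function(ph, calib, r_range = calib$r_range) {
  calib$alpha_system *
    (r_range / (1 + exp(calib$alpha_ph * (ph - calib$pka))) + calib$r_cte)
}

#' @export
predict.ph_calibration <- function(object, ph, r_range = object$r_range, ...) {
  ph_forward(ph, object, r_range = r_range)
}

#' Background-subtracted fluorescence ratio
#'
#' \eqn{FR = (F_{Red} - F_{RedBg}) / (F_{Green} - F_{GreenBg})}, pointwise.
#'
#' @param red,green [vd_trace]s of the two channels (shared grid).
#' @param red_bg,green_bg channel backgrounds, a.u.
#' @return a dimensionless [vd_trace] of FR.
#' @export
fluorescence_ratio <- function(red, green, red_bg = 0, green_bg = 0) {
  stopifnot(inherits(red, "vd_trace"), inherits(green, "vd_trace"))
  if (length(red$value) != length(green$value) || red$fs != green$fs)
    vd_stop("invalid_parameter", "red and green traces must share a grid")
  g <- green$value - green_bg
  bad <- which(g <= 0)
  if (length(bad))
    vd_stop("division", "green channel at/below background at sample %d", bad[1])
  vd_trace((red$value - red_bg) / g, fs = red$fs, t0 = red$time[1],
           units = "FR", baseline_window = red$baseline_window)
}

#' Fit the FR-vs-pH sigmoid to a calibration lookup table
#'
#' Least-squares fit of the calibration sigmoid with `r_range`, `r_cte`,
#' `alpha_ph` and `pka` free and `alpha_system` fixed (an instrument constant).
#' Starts: pKa at the median calibration pH, slope 2, offset min(FR)/alpha.
#'
#' @param ph_values calibration pH points (>= 5, spanning the inflection).
#' @param fr_values measured FR at each point.
#' @param alpha_system fixed instrument constant.
#' @param start optional named list overriding the default initial guesses
#'   (`r_range`, `r_cte`, `alpha_ph`, `pka`).
#' @return a [ph_calibration()] with `r_squared` and `fit_cov` filled in.
#' @export
fit_ph_calibration <- function(ph_values, fr_values, alpha_system = 1,
                               start = NULL) {
  ph <- as.numeric(ph_values); fr <- as.numeric(fr_values)
  if (length(ph) != length(fr) || length(ph) < 5L)
    vd_stop("calibration", "need at least 5 calibration points")
  s <- list(pka = stats::median(ph), alpha_ph = 2,
            r_cte = min(fr) / alpha_system,
            r_range = diff(range(fr)) / alpha_system)
  if (!is.null(start)) s[names(start)] <- start
  fn <- function(p) {
    fr - alpha_system *
      (p[1] / (1 + exp(p[3] * (ph - p[4]))) + p[2])
  }
  p0 <- c(s$r_range, s$r_cte, s$alpha_ph, s$pka)
  res <- tryCatch(
    minpack.lm::nls.lm(p0, lower = c(1e-6, 0, 1e-3, 4), upper = c(Inf, Inf, 50, 11),
                       fn = fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(res) || !res$info %in% 1:4)
    vd_stop("calibration", "calibration sigmoid fit did not converge")
  p <- res$par
  ss_res <- sum(res$fvec^2)
  ss_tot <- sum((fr - mean(fr))^2)
  covm <- tryCatch(
    ss_res / (length(fr) - 4) * solve(res$hessian / 2),
    error = function(e) NULL)
  ph_calibration(alpha_ph = p[3], pka = p[4], r_cte = p[2],
                 alpha_system = alpha_system, r_range = p[1],
                 r_squared = 1 - ss_res / ss_tot, fit_cov = covm)
}

#' Per-recording dynamic range from the baseline ratio
#'
#' Anchors each recording to an assumed baseline blood pH (7.4):
#' \deqn{R_{Range} = \left(\frac{FR_{Baseline}}{\alpha_{sys}} - R_{Cte}\right)
#'   \left(1 + e^{\alpha_{pH}(pH_{base} - pKa)}\right).}
#'
#' @param fr_baseline mean FR over the baseline window, or a [vd_trace] of FR
#'   (its baseline-window mean is then used).
#' @param calib a [ph_calibration()].
#' @param ph_baseline assumed baseline blood pH (default 7.4).
#' @return list of class `ph_recording`: `r_range`, `fr_baseline`,
#'   `ph_baseline`.
#' @export
r_range_from_baseline <- function(fr_baseline, calib, ph_baseline = 7.4) {
  stopifnot(inherits(calib, "ph_calibration"))
  if (inherits(fr_baseline, "vd_trace"))
    fr_baseline <- mean(fr_baseline$value[baseline_idx(fr_baseline)])
  core <- fr_baseline / calib$alpha_system - calib$r_cte
  if (core <= 0)
    vd_stop("out_of_range",
            "baseline FR at/below the pH-insensitive floor (FR/alpha <= R_Cte)")
  r_range <- core * (1 + exp(calib$alpha_ph * (ph_baseline - calib$pka)))
  structure(list(r_range = r_range, fr_baseline = fr_baseline,
                 ph_baseline = ph_baseline),
            class = "ph_recording")
}

#' Invert the ratio trace to pH
#'
#' \deqn{pH = pKa + \frac{1}{\alpha_{pH}}
#'   \ln\!\left(\frac{R_{Range}}{FR/\alpha_{sys} - R_{Cte}} - 1\right).}
#' Samples whose log argument is non-positive (ratio at/beyond the sigmoid
#' gamut, e.g. clipped transients) are returned as NA and counted in the
#' `out_of_gamut` attribute rather than raising an error.
#'
#' @param fr a [vd_trace] of FR (or numeric vector).
#' @param calib a [ph_calibration()].
#' @param rec a `ph_recording` from [r_range_from_baseline()].
#' @return a [vd_trace] of pH (or numeric vector), with attribute
#'   `out_of_gamut` giving the masked sample indices.
#' @export
ph_from_ratio <- function(fr, calib, rec) {
  stopifnot(inherits(calib, "ph_calibration"), inherits(rec, "ph_recording"))
  v <- if (inherits(fr, "vd_trace")) fr$value else as.numeric(fr)
  core <- v / calib$alpha_system - calib$r_cte
  arg <- rec$r_range / core - 1
  bad <- which(!(core > 0 & arg > 0))
  arg[bad] <- NA_real_
  ph <- calib$pka + log(arg) / calib$alpha_ph
  if (inherits(fr, "vd_trace")) {
    out <- vd_trace(ph, fs = fr$fs, t0 = fr$time[1], units = "pH",
                    baseline_window = fr$baseline_window)
  } else out <- ph
  attr(out, "out_of_gamut") <- bad
  out
}

#' Summarise a pH transient
#'
#' Baseline mean, the extremum inside the stimulus window, and the signed
#' change from baseline; the onset of the acidification can be obtained
#' separately via [fit_response()] / [onset_from_fit()] on the z-scored trace.
#'
#' @param ph_trace a [vd_trace] of pH.
#' @param stim_window c(t1, t2), seconds, window searched for the extremum.
#' @param direction `"min"` (acidification, default) or `"max"`.
#' @param smooth_s running-mean width applied before the extremum, seconds
#'   (default 1; suppresses the extreme-value bias a pointwise min/max would
#'   pick up from shot noise).
#' @return list with `baseline_ph`, `extreme_ph`, `delta_ph`, `extreme_time`.
#' @export
delta_ph_summary <- function(ph_trace, stim_window, direction = c("min", "max"),
                             smooth_s = 1) {
  stopifnot(inherits(ph_trace, "vd_trace"))
  direction <- match.arg(direction)
  x <- ph_trace$value
  w <- max(1L, round(smooth_s * ph_trace$fs))
  if (w > 1L) {
    sm <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
    x[!is.na(sm)] <- sm[!is.na(sm)]
  }
  inside <- ph_trace$time >= stim_window[1] & ph_trace$time <= stim_window[2]
  v <- x[inside]
  if (!length(v) || all(is.na(v)))
    vd_stop("invalid_parameter", "stimulus window empty or all out-of-gamut")
  base <- mean(ph_trace$value[baseline_idx(ph_trace)], na.rm = TRUE)
  i <- if (direction == "min") which.min(v) else which.max(v)
  list(baseline_ph = base, extreme_ph = v[i], delta_ph = v[i] - base,
       extreme_time = ph_trace$time[inside][i])
}
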