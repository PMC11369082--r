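# Paired-stimulation occlusion analysis: does the measured response to
# combined stimuli equal the sum of the separately measured responses
# (additivity), or fall short (occlusion / saturation of shared machinery)?

#' Simulate a paired-stimulation occlusion experiment
#'
#' Builds a complete synthetic paired-stimulation dataset: two component
#' responses (a fast whisker/NVC dilation and a slower hypercapnic dilation,
#' stimuli at 10 s), each measured separately over `component_trials` noisy
#' trials and averaged; a calculated-summation trace from the averages; and
#' `n_trials` experimental paired-stimulus trials whose ground truth is
#' either the pointwise sum of the two components (`"additive"`) or their
#' pointwise maximum (`"occlusive"`, emulating saturation of shared
#' machinery).
#'
#' @param seed integer RNG seed.
#' @param combine `"additive"` or `"occlusive"` ground truth.
#' @param lag seconds between CO2 onset and whisker onset (0 or 2).
#' @param n_trials experimental paired trials.
#' @param component_trials trials per separately measured component.
#' @param noise_sd per-trial noise SD, trace units.
#' @return list with `trials` (list of z [vd_trace]s), `calculated`
#'   ([vd_trace]), `window` (the AUC analysis window: 10-17 s, shifted to
#'   12-19 s when `lag = 2`), and `truth`.
#' @export
gen_paired_trialset <- function(seed, combine = c("additive", "occlusive"),
                                lag = 0, n_trials = 8, component_trials = 8,
                                noise_sd = 0.5) {
  combine <- match.arg(combine)
  co2_model <- list(amplitude = 5, tau_rise = 0.5, tau_decay = 10)
  ws_model <- list(amplitude = 8, tau_rise = 0.5, tau_decay = 4)
  mk <- function(model, onset, s) {
    zscore(gen_response_trace(response_model = model, onset_true = onset,
                              noise_sd = noise_sd, duration = 30, fs = 10,
                              seed = s)$trace)
  }
  co2_avg <- average_trials(lapply(seq_len(component_trials), function(i)
    mk(co2_model, 15.8, seed + i)))$mean
  ws_avg <- average_trials(lapply(seq_len(component_trials), function(i)
    mk(ws_model, 10.8, seed + 100 + i)))$mean
  calc <- calculated_summation(co2_avg, ws_avg, lag = lag)
  trials <- lapply(seq_len(n_trials), function(i) {
    a <- mk(co2_model, 15.8, seed + 200 + i)
    b <- mk(ws_model, 10.8 + lag, seed + 300 + i)
    v <- if (combine == "additive") a$value + b$value else pmax(a$value, b$value)
    vd_trace(v, fs = a$fs, units = "z", baseline_window = a$baseline_window)
  })
  # held-out single-trial summations for exact trial-wise pairing
  calc_trials <- lapply(seq_len(n_trials), function(i)
    calculated_summation(mk(co2_model, 15.8, seed + 400 + i),
                         mk(ws_model, 10.8, seed + 500 + i), lag = lag))
  list(trials = trials, calculated = calc, calculated_trials = calc_trials,
       window = c(10, 17) + lag,
       truth = list(combine = combine, lag = lag, seed = seed))
}

#' Calculated summation of two component responses
#'
#' `resp_a(t) + resp_b(t - lag)`, with `resp_b` zero-padded outside its own
#' support, interpolated onto a common 0.1 s grid over `resp_a`'s support.
#' Both traces must be baseline-referenced (z or delta units).
#'
#' @param resp_a,resp_b [vd_trace]s, baseline-referenced.
#' @param lag seconds by which `resp_b` is delayed (>= 0).
#' @param grid_step output grid step, seconds (default 0.1).
#' @return a [vd_trace] on the common grid.
#' @export
calculated_summation <- function(resp_a, resp_b, lag = 0, grid_step = 0.1) {
  stopifnot(inherits(resp_a, "vd_trace"), inherits(resp_b, "vd_trace"))
  if (lag < 0) vd_stop("invalid_parameter", "lag must be >= 0")
  a1 <- resp_a$time[1]; a2 <- max(resp_a$time)
  b1 <- resp_b$time[1] + lag; b2 <- max(resp_b$time) + lag
  if (b1 >= a2 || b2 <= a1)
    vd_stop("out_of_support", "no temporal overlap between the two responses")
  grid <- seq(a1, a2, by = grid_step)
  va <- interp_trace(resp_a, grid)
  tb <- grid - lag
  vb <- rep(0, length(grid))
  inb <- tb >= resp_b$time[1] - 1e-9 & tb <= max(resp_b$time) + 1e-9
  vb[inb] <- interp_trace(resp_b, tb[inb])
  bw <- c(max(resp_a$baseline_window[1], a1),
          min(resp_a$baseline_window[2], a2))
  vd_trace(va + vb, fs = 1 / grid_step, t0 = grid[1], units = resp_a$units,
           baseline_window = bw)
}

#' Wilcoxon test with exact small-sample null
#'
#' Signed-rank (paired / one-sample) or rank-sum (two-sample) Wilcoxon test;
#' the exact permutation null is used for small samples without ties
#' (n <= 25), the normal approximation with continuity correction otherwise.
#'
#' @param x numeric: paired differences (signed-rank) or first sample.
#' @param y optional second sample (rank-sum), or paired second measurements
#'   (signed-rank).
#' @param mode `"signed-rank"` or `"rank-sum"`.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return list with `statistic`, `p_value`, `method`.
#' @export
wilcoxon_test <- function(x, y = NULL,
                          mode = c("signed-rank", "rank-sum"),
                          alternative = c("two.sided", "less", "greater")) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  if (mode == "signed-rank") {
    d <- if (is.null(y)) x else x - y
    d <- d[d != 0 | is.na(d)]
    if (length(d) < 4L)
      vd_stop("invalid_parameter", "need >= 4 nonzero paired differences")
    if (all(d == 0)) vd_stop("degenerate", "all paired differences are zero")
    ht <- stats::wilcox.test(d, alternative = alternative,
                             exact = length(d) <= 25L, correct = TRUE)
  } else {
    if (is.null(y) || length(x) < 4L || length(y) < 4L)
      vd_stop("invalid_parameter", "rank-sum mode needs two samples of >= 4")
    ht <- stats::wilcox.test(x, y, alternative = alternative,
                             exact = max(length(x), length(y)) <= 25L,
                             correct = TRUE)
  }
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = ht$method)
}

#' Compare experimental paired responses with their calculated summation
#'
#' AUC of every experimental trial and of the calculated-summation trace over
#' the analysis window (10-17 s for simultaneous stimuli, 12-19 s when the
#' second stimulus is delayed by 2 s), followed by a paired Wilcoxon
#' signed-rank test of the per-trial differences (experimental - calculated).
#' The one-sided `"less"` alternative tests for sub-additivity (occlusion).
#'
#' @param experimental list of [vd_trace]s (trials of the paired-stimulus
#'   response).
#' @param calculated a [vd_trace] from [calculated_summation()] (every trial
#'   is compared against this one averaged reference), or a list of
#'   per-trial calculated traces of the same length as `experimental`
#'   (trial-wise pairing; under additive ground truth the paired differences
#'   are then exactly symmetric about zero, so the signed-rank test holds its
#'   nominal level).
#' @param window c(t1, t2), seconds.
#' @param alternative test alternative (default `"two.sided"`; use `"less"`
#'   for a one-sided sub-additivity test).
#' @param mode `"signed-rank"` (default) or `"rank-sum"`.
#' @return list with `auc_exp` (per trial), `auc_calc`, `mean_difference`,
#'   `pct_of_calculated`, `statistic`, `p_value` (NA with a warning when
#'   fewer than 4 trials).
#' @export
compare_summation <- function(experimental, calculated, window,
                              alternative = c("two.sided", "less", "greater"),
                              mode = c("signed-rank", "rank-sum")) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  if (window[2] <= window[1])
    vd_stop("invalid_parameter", "analysis window must have positive length")
  auc_exp <- vapply(experimental, auc, numeric(1), window = window)
  if (inherits(calculated, "vd_trace")) {
    auc_calc <- auc(calculated, window)
  } else {
    if (length(calculated) != length(experimental))
      vd_stop("invalid_parameter",
              "trial-wise calculated traces must match the experimental trials")
    auc_calc <- vapply(calculated, auc, numeric(1), window = window)
  }
  d <- auc_exp - auc_calc
  test <- if (length(d) >= 4L) {
    if (mode == "signed-rank") wilcoxon_test(d, mode = mode,
                                             alternative = alternative)
    else wilcoxon_test(auc_exp, rep_len(auc_calc, length(auc_exp)),
                       mode = mode, alternative = alternative)
  } else {
    warning("fewer than 4 trials; Wilcoxon test skipped")
    list(statistic = NA_real_, p_value = NA_real_, method = "skipped")
  }
  list(auc_exp = auc_exp, auc_calc = auc_calc,
       mean_difference = mean(d),
       pct_of_calculated = 100 * mean(auc_exp) / mean(auc_calc),
       statistic = test$statistic, p_value = test$p_value,
       method = test$method)
}
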