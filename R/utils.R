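# Internal helpers: classed errors, seeded RNG scoping, peak detection.

#' @keywords internal
vd_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("vasodyn_", class), "vasodyn_error")))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    vd_stop("invalid_parameter", "seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Local extrema with prominence, in the spirit of scipy.signal.find_peaks.
# Prominence of a peak: height above the higher of the two deepest valleys
# separating it from a higher peak (or the record edge) on either side.
#' @keywords internal
find_peaks <- function(x, min_prominence = 0, min_distance = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (!length(idx)) return(integer(0))
  prom <- vapply(idx, function(i) {
    # walk left until a sample higher than the peak (or the edge)
    lo_l <- x[i]
    j <- i - 1L
    while (j >= 1L && x[j] <= x[i]) { lo_l <- min(lo_l, x[j]); j <- j - 1L }
    lo_r <- x[i]
    j <- i + 1L
    while (j <= n && x[j] <= x[i]) { lo_r <- min(lo_r, x[j]); j <- j + 1L }
    x[i] - max(lo_l, lo_r)
  }, numeric(1))
  keep <- prom >= min_prominence
  idx <- idx[keep]; prom <- prom[keep]
  if (min_distance > 1L && length(idx) > 1L) {
    # greedy: keep the most prominent, drop neighbours within min_distance
    ord <- order(prom, decreasing = TRUE)
    taken <- logical(length(idx))
    sel <- logical(length(idx))
    for (k in ord) {
      if (!taken[k]) {
        sel[k] <- TRUE
        taken[abs(idx - idx[k]) < min_distance] <- TRUE
      }
    }
    idx <- sort(idx[sel])
  }
  idx
}

#' @keywords internal
find_valleys <- function(x, min_prominence = 0, min_distance = 1L) {
  find_peaks(-x, min_prominence = min_prominence, min_distance = min_distance)
}

# 3-point parabolic interpolation around a discrete argmax; returns the
# sub-sample offset in (-0.5, 0.5) (0 when the vertex is degenerate).
#' @keywords internal
parabolic_offset <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (!is.finite(den) || den == 0) return(0)
  off <- 0.5 * (ym1 - yp1) / den
  max(-0.5, min(0.5, off))
}
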