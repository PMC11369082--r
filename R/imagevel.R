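# Vessel diameter, lumen area and RBC velocity extraction from line-scan
# kymographs and frame movies.

#' Full-width-at-half-maximum vessel diameter from an intensity profile
#'
#' The reference levels are robust to streak-induced dips: background is the
#' mean of the outer 10% of the profile, the lumen plateau is the 95th
#' percentile of the bright region. The two half-maximum crossings are located
#' with linear sub-pixel interpolation.
#'
#' @param profile intensity over position (numeric vector).
#' @param px_size pixel size, um.
#' @return diameter in um.
#' @examples
#' p <- c(rep(0, 10), rep(1, 10), rep(0, 10))
#' diameter_fwhm(p, px_size = 0.5)
#' @export
diameter_fwhm <- function(profile, px_size = 1) {
  n <- length(profile)
  if (n < 5L) vd_stop("no_vessel", "profile too short")
  k <- max(1L, floor(0.1 * n))
  bg <- mean(c(profile[seq_len(k)], profile[(n - k + 1L):n]))
  top <- max(profile)
  if (top <= bg)
    vd_stop("no_vessel", "no lumen found: profile has no region above background")
  # plateau: 95th percentile of the lumen core (top 20% band), robust to
  # streak-induced intensity dips without narrowing a sharp peak
  core <- profile[profile >= bg + 0.8 * (top - bg)]
  plateau <- stats::quantile(core, 0.95, names = FALSE)
  if (!is.finite(plateau) || plateau <= bg)
    vd_stop("no_vessel", "no lumen found: profile has no region above background")
  half <- bg + (plateau - bg) / 2
  above <- profile >= half
  if (!any(above)) vd_stop("no_vessel", "no half-maximum crossing found")
  i1 <- which(above)[1]
  i2 <- which(above)[sum(above)]
  # linear sub-pixel interpolation at both crossings
  left <- if (i1 > 1L)
    (i1 - 1) + (half - profile[i1 - 1L]) / (profile[i1] - profile[i1 - 1L])
  else i1 - 0.5
  right <- if (i2 < n)
    i2 + (profile[i2] - half) / (profile[i2] - profile[i2 + 1L])
  else i2 + 0.5
  (right - left) * px_size
}

#' Diameter time series from a transverse kymograph
#'
#' Applies [diameter_fwhm()] row-wise (optionally in blocks of averaged lines).
#'
#' @param kymo a [vd_kymograph] with transverse orientation.
#' @param smoothing_window lines averaged per diameter sample (>= 1).
#' @return a [vd_trace] of diameters in um.
#' @export
diameter_timeseries <- function(kymo, smoothing_window = 1L) {
  stopifnot(inherits(kymo, "vd_kymograph"))
  if (kymo$orientation != "transverse")
    vd_stop("invalid_parameter", "diameter_timeseries requires a transverse kymograph")
  nl <- nrow(kymo$data)
  w <- max(1L, as.integer(smoothing_window))
  starts <- seq(1L, nl - w + 1L, by = w)
  d <- vapply(starts, function(i) {
    prof <- colMeans(kymo$data[i:(i + w - 1L), , drop = FALSE])
    tryCatch(diameter_fwhm(prof, kymo$px_size),
             vasodyn_no_vessel = function(e)
               vd_stop("no_vessel", "no vessel at lines %d-%d: %s",
                       i, i + w - 1L, conditionMessage(e)))
  }, numeric(1))
  fs <- kymo$line_rate / w
  dur <- length(d) / fs
  vd_trace(d, fs = fs, units = "um",
           baseline_window = c(0, min(9, dur * 0.9)))
}

#' Lumen area and equivalent diameter from a frame movie
#'
#' Threshold is computed once (Otsu) on the mean of the baseline frames and
#' held fixed across the movie, so apparent dilation cannot arise from
#' per-frame threshold drift. Per frame, the largest connected bright
#' component is hole-filled and its pixel count converted to area.
#'
#' @param movie 3-D array, frame x rows x cols.
#' @param px_size pixel size, um.
#' @param frame_rate frames per second, Hz.
#' @param baseline_frames indices used for the threshold reference (default:
#'   first third of the movie).
#' @param min_px minimum component size, px, below which segmentation fails.
#' @return list with `area` ([vd_trace], um^2) and `eq_diameter` ([vd_trace],
#'   um; \eqn{2\sqrt{A/\pi}}).
#' @export
lumen_area_timeseries <- function(movie, px_size = 1, frame_rate = 3,
                                  baseline_frames = NULL, min_px = 9L) {
  d <- dim(movie)
  if (length(d) != 3L) vd_stop("invalid_parameter", "movie must be frame x rows x cols")
  nf <- d[1]
  if (is.null(baseline_frames)) baseline_frames <- seq_len(max(1L, nf %/% 3L))
  ref <- apply(movie[baseline_frames, , , drop = FALSE], c(2, 3), mean)
  rng <- range(ref)
  if (diff(rng) <= 0) vd_stop("segmentation", "blank reference image")
  thr <- EBImage::otsu(EBImage::Image((ref - rng[1]) / diff(rng)))
  areas <- vapply(seq_len(nf), function(f) {
    fr <- (movie[f, , ] - rng[1]) / diff(rng)
    bw <- EBImage::fillHull(EBImage::bwlabel(fr > thr))
    tab <- tabulate(as.integer(bw))
    if (!length(tab) || max(tab) < min_px)
      vd_stop("segmentation", "no lumen component in frame %d", f)
    comp <- EBImage::fillHull(bw == which.max(tab))
    sum(comp > 0) * px_size^2
  }, numeric(1))
  dur <- nf / frame_rate
  bw_win <- c(0, min(9, dur * 0.9))
  list(area = vd_trace(areas, fs = frame_rate, units = "um^2",
                       baseline_window = bw_win),
       eq_diameter = vd_trace(2 * sqrt(areas / pi), fs = frame_rate,
                              units = "um", baseline_window = bw_win))
}

#' Line-scanning PIV velocity from a longitudinal kymograph
#'
#' Classic LSPIV: line groups separated by `line_sep` scan lines are
#' cross-correlated; the displacement is the correlation argmax refined with
#' 3-point Gaussian (log-parabolic) sub-pixel interpolation -- the standard
#' PIV peak estimator, unbiased for the near-Gaussian streak correlation peak
#' -- and velocity = displacement/line_sep x px_size x line_rate (signed;
#' positive towards increasing column index). Blocks whose correlation peak
#' sits on the search boundary are flagged unreliable rather than clipped.
#'
#' @param kymo a [vd_kymograph], longitudinal orientation.
#' @param block_lines lines per block (default 25, 50% overlap).
#' @param search_px maximum displacement searched, px (default: quarter scan
#'   length).
#' @param line_sep line separation between the correlated groups (default 4;
#'   larger values trade temporal resolution for sub-pixel precision at slow
#'   flow).
#' @return data.frame with `time` (s), `velocity` (mm/s), `quality` (normalised
#'   correlation peak in [0,1]) and `reliable` (logical).
#' @export
lspiv_velocity <- function(kymo, block_lines = 25L, search_px = NULL,
                           line_sep = 4L) {
  stopifnot(inherits(kymo, "vd_kymograph"))
  if (kymo$orientation != "longitudinal")
    vd_stop("invalid_parameter", "lspiv_velocity requires a longitudinal kymograph")
  img <- kymo$data
  nl <- nrow(img); np <- ncol(img)
  if (block_lines < 2L) vd_stop("invalid_parameter", "block_lines must be >= 2")
  if (nl < block_lines + line_sep)
    vd_stop("invalid_parameter", "kymograph shorter than one block")
  if (is.null(search_px)) search_px <- max(2L, np %/% 4L)
  step <- max(1L, block_lines %/% 2L)
  starts <- seq(1L, nl - block_lines - line_sep + 1L, by = step)
  shifts <- (-search_px):search_px
  res <- lapply(starts, function(i) {
    a <- img[i:(i + block_lines - 1L), , drop = FALSE]
    b <- img[(i + line_sep):(i + block_lines + line_sep - 1L), , drop = FALSE]
    a <- a - mean(a); b <- b - mean(b)
    cc <- vapply(shifts, function(s) {
      ia <- max(1L, 1L - s):min(np, np - s)
      ib <- ia + s
      va <- as.vector(a[, ia]); vb <- as.vector(b[, ib])
      sa <- sqrt(sum(va^2)); sb <- sqrt(sum(vb^2))
      if (sa == 0 || sb == 0) 0 else sum(va * vb) / (sa * sb)
    }, numeric(1))
    j <- which.max(cc)
    boundary <- j == 1L || j == length(shifts)
    off <- if (boundary) 0 else {
      y <- cc[(j - 1L):(j + 1L)]
      if (all(y > 0)) {
        ly <- log(y)
        den <- ly[1] - 2 * ly[2] + ly[3]
        if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (ly[1] - ly[3]) / den))
      } else parabolic_offset(y[1], y[2], y[3])
    }
    disp <- (shifts[j] + off) / line_sep                     # px per line
    data.frame(time = (i + (block_lines + line_sep) / 2) / kymo$line_rate,
               velocity = disp * kymo$px_size * kymo$line_rate / 1000,
               quality = max(0, min(1, cc[j])),
               reliable = !boundary)
  })
  do.call(rbind, res)
}

#' Streak-angle velocity from a kymograph
#'
#' Radon-style orientation search: the image is sheared by a candidate
#' per-line displacement and the variance of its column sums is maximised
#' (streaks aligned with the shear concentrate into sharp columns). A coarse
#' grid is refined by golden-section search. Velocity follows from the best
#' shear slope as px_size x line_rate x slope; an image with no dominant
#' orientation raises a no-flow error.
#'
#' @param kymo a [vd_kymograph].
#' @param max_disp_px maximum per-line displacement searched (default 4 px).
#' @param anisotropy_min minimum (max/mean - 1) variance contrast accepted
#'   (default 2; white noise stays below ~1, real streaks score above 10).
#' @return list with `velocity` (mm/s), `slope_px_per_line`, `quality`.
#' @export
streak_angle_velocity <- function(kymo, max_disp_px = 4, anisotropy_min = 2) {
  stopifnot(inherits(kymo, "vd_kymograph"))
  img <- kymo$data - mean(kymo$data)
  nl <- nrow(img); np <- ncol(img)
  proj_var <- function(slope) {
    # shear rows by -slope*t and sum down columns (linear interp, circular)
    acc <- numeric(np)
    for (i in seq_len(nl)) {
      sh <- ((i - 1) * slope) %% np
      s0 <- floor(sh); frac <- sh - s0
      k0 <- ((seq_len(np) - 1L + s0) %% np) + 1L
      k1 <- (k0 %% np) + 1L
      acc <- acc + (1 - frac) * img[i, k0] + frac * img[i, k1]
    }
    stats::var(acc)
  }
  grid <- seq(-max_disp_px, max_disp_px, length.out = 41L)
  vs <- vapply(grid, proj_var, numeric(1))
  j <- which.max(vs)
  contrast <- max(vs) / mean(vs) - 1
  if (!is.finite(contrast) || contrast < anisotropy_min)
    vd_stop("no_flow", "no dominant streak orientation (contrast %.3f)", contrast)
  lo <- grid[max(1L, j - 1L)]; hi <- grid[min(length(grid), j + 1L)]
  opt <- stats::optimize(proj_var, c(lo, hi), maximum = TRUE, tol = 1e-4)
  slope <- opt$maximum                                       # px per line
  list(velocity = slope * kymo$px_size * kymo$line_rate / 1000,
       slope_px_per_line = slope,
       quality = min(1, contrast / (contrast + 1)))
}

#' Rigid realignment of a frame movie by ROI cross-correlation
#'
#' Each frame is translated by the integer shift maximising the
#' cross-correlation of its ROI with the reference (first-frame) ROI;
#' sub-pixel refinement is deliberately not applied.
#'
#' @param movie 3-D array, frame x rows x cols.
#' @param roi c(row1, row2, col1, col2) rectangle within the frame.
#' @param max_shift largest shift searched in each direction, px.
#' @return list with `movie` (realigned array), `shifts` (frame x 2 matrix of
#'   (row, col) shifts) and `failed` (frames whose best shift hit the bound).
#' @export
realign_frames <- function(movie, roi, max_shift = 5L) {
  d <- dim(movie)
  if (length(d) != 3L) vd_stop("invalid_parameter", "movie must be frame x rows x cols")
  roi <- as.integer(roi)
  if (roi[1] < 1L || roi[3] < 1L || roi[2] > d[2] || roi[4] > d[3] ||
      roi[1] >= roi[2] || roi[3] >= roi[4])
    vd_stop("invalid_parameter", "roi outside frame bounds")
  ref <- movie[1, roi[1]:roi[2], roi[3]:roi[4]]
  ref <- ref - mean(ref)
  shifts <- matrix(0L, d[1], 2)
  failed <- logical(d[1])
  out <- movie
  rng <- (-max_shift):max_shift
  for (f in seq_len(d[1])) {
    fr <- movie[f, , ]
    best <- -Inf; br <- 0L; bc <- 0L
    for (dr in rng) for (dc in rng) {
      r1 <- roi[1] + dr; r2 <- roi[2] + dr
      c1 <- roi[3] + dc; c2 <- roi[4] + dc
      if (r1 < 1L || c1 < 1L || r2 > d[2] || c2 > d[3]) next
      w <- fr[r1:r2, c1:c2]
      w <- w - mean(w)
      den <- sqrt(sum(w^2) * sum(ref^2))
      sc <- if (den == 0) 0 else sum(w * ref) / den
      if (sc > best) { best <- sc; br <- dr; bc <- dc }
    }
    failed[f] <- abs(br) == max_shift || abs(bc) == max_shift
    shifts[f, ] <- c(br, bc)
    if (br != 0L || bc != 0L) {
      shifted <- array(NA_real_, dim(fr))
      rs <- seq_len(d[2]) + br; cs <- seq_len(d[3]) + bc
      ok_r <- rs >= 1L & rs <= d[2]; ok_c <- cs >= 1L & cs <= d[3]
      shifted[which(ok_r), which(ok_c)] <- fr[rs[ok_r], cs[ok_c]]
      out[f, , ] <- shifted
    }
  }
  list(movie = out, shifts = shifts, failed = which(failed))
}

#' Fractional fluorescence change (dF/F)
#'
#' \eqn{\Delta F / F = (F - F_0)/F_0} with \eqn{F_0} the mean over the trace's
#' declared baseline window.
#'
#' @param trace a [vd_trace].
#' @return a dimensionless [vd_trace].
#' @export
dff <- function(trace) {
  stopifnot(inherits(trace, "vd_trace"))
  f0 <- mean(trace$value[baseline_idx(trace)])
  if (!is.finite(f0) || f0 == 0)
    vd_stop("division", "baseline fluorescence F0 is zero")
  vd_trace((trace$value - f0) / f0, fs = trace$fs, t0 = trace$time[1],
           units = "dF/F", baseline_window = trace$baseline_window)
}
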