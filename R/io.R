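# Readers and writers. Traces travel as CSV (time_s,value) with a JSON
# sidecar for units/rate/baseline; kymographs and fUS ensembles as float
# multi-page TIFF with a JSON sidecar carrying acquisition metadata and the
# affine rescaling (TIFF float storage is [0,1]).

#' @keywords internal
sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a trace as CSV + JSON sidecar
#'
#' @param trace a [vd_trace].
#' @param path CSV file path; metadata goes to `<path>.json`.
#' @return `write_trace` returns `path` invisibly; `read_trace` a [vd_trace].
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "vd_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  jsonlite::write_json(list(units = trace$units, fs = trace$fs,
                            t0 = trace$time[1],
                            baseline_window = trace$baseline_window),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  vd_trace(df$value, fs = meta$fs, t0 = meta$t0, units = meta$units,
           baseline_window = meta$baseline_window)
}

# Normalise a numeric array to [0,1]; returns list(x, lo, hi).
#' @keywords internal
norm01 <- function(x) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) hi <- lo + 1
  list(x = (x - lo) / (hi - lo), lo = lo, hi = hi)
}

#' Write / read a kymograph as float TIFF + JSON sidecar
#'
#' Rows are scan lines (time), columns position; line rate, pixel size,
#' orientation and the intensity rescaling live in the sidecar.
#'
#' @param kymo a [vd_kymograph].
#' @param path TIFF file path.
#' @export
write_kymograph <- function(kymo, path) {
  stopifnot(inherits(kymo, "vd_kymograph"))
  nm <- norm01(kymo$data)
  tiff::writeTIFF(nm$x, path, bits.per.sample = 32L)
  jsonlite::write_json(list(line_rate_hz = kymo$line_rate,
                            px_size_um = kymo$px_size,
                            orientation = kymo$orientation,
                            value_min = nm$lo, value_max = nm$hi),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_kymograph
#' @export
read_kymograph <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  x <- tiff::readTIFF(path)
  x <- x * (meta$value_max - meta$value_min) + meta$value_min
  vd_kymograph(x, line_rate = meta$line_rate_hz, px_size = meta$px_size_um,
               orientation = meta$orientation)
}

#' Write / read an fUS ensemble as multi-page float TIFF + JSON sidecar
#'
#' One TIFF page per slow-time frame; `frame_rate_hz`, `center_freq_mhz` and
#' the intensity rescaling live in the sidecar.
#'
#' @param ens a [vd_fus_ensemble].
#' @param path TIFF file path.
#' @export
write_fus <- function(ens, path) {
  stopifnot(inherits(ens, "vd_fus_ensemble"))
  nm <- norm01(ens$frames)
  pages <- lapply(seq_len(dim(nm$x)[1]), function(i) nm$x[i, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(frame_rate_hz = ens$frame_rate,
                            center_freq_mhz = ens$center_freq,
                            value_min = nm$lo, value_max = nm$hi),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fus
#' @export
read_fus <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, c(length(pages), dim(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  arr <- arr * (meta$value_max - meta$value_min) + meta$value_min
  vd_fus_ensemble(arr, frame_rate = meta$frame_rate_hz,
                  center_freq = meta$center_freq_mhz)
}

#' Write / read a pH calibration model as JSON
#' @param calib a [ph_calibration()].
#' @param path JSON file path.
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "ph_calibration"))
  jsonlite::write_json(list(alpha_ph = calib$alpha_ph, pka = calib$pka,
                            r_cte = calib$r_cte,
                            alpha_system = calib$alpha_system,
                            r_range = calib$r_range,
                            r_squared = calib$r_squared),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  ph_calibration(alpha_ph = m$alpha_ph, pka = m$pka, r_cte = m$r_cte,
                 alpha_system = m$alpha_system, r_range = m$r_range,
                 r_squared = if (is.null(m$r_squared)) NA_real_ else m$r_squared)
}

#' Read a run configuration (YAML or JSON)
#'
#' Fills defaults for missing fields: seed 1, stimulus at 10 s (briefCO2 20%,
#' 10 s), 9 s baseline [1, 10) s, onset rule `fit` with fraction 0.1.
#'
#' @param path YAML or JSON file, or a named list (returned with defaults
#'   applied).
#' @return named list of class `vd_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  defaults <- list(seed = 1L, stim_time = 10, stim_duration = 10,
                   baseline_window = c(1, 10), onset_rule = "fit",
                   onset_fraction = 0.1, lag = 0, out_dir = tempfile("vasodyn_"),
                   calibration = NULL)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (!is.null(cfg$calibration) && is.character(cfg$calibration)) {
    if (!file.exists(cfg$calibration))
      vd_stop("config", "calibration file not found: %s", cfg$calibration)
    cfg$calibration <- read_calibration(cfg$calibration)
  }
  structure(cfg, class = "vd_config")
}
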