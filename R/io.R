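# Plain-text containers: spectra as CSV (axis, intensity) with a JSON
# metadata sidecar or as a single JSON document, peak lists and relaxation
# series as CSV.

#' Write / read a 1D spectrum as CSV + JSON metadata
#'
#' `write_spectrum1d` writes `<path>` as two-column CSV (`ppm`,
#' `intensity`) and `<path>.json` with the spectrometer metadata;
#' `read_spectrum1d` reverses it.
#'
#' @param spectrum A `spectrum1d`.
#' @param path CSV path.
#' @return The path (write) or a `spectrum1d` (read).
#' @export
write_spectrum1d <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  utils::write.csv(data.frame(ppm = spectrum$ppm,
                              intensity = spectrum$intensity),
                   path, row.names = FALSE)
  meta <- spectrum[setdiff(names(spectrum), c("ppm", "intensity"))]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spectrum1d
#' @export
read_spectrum1d <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  .new_spectrum1d(df$ppm, df$intensity,
                  meta$nucleus %||% "13C",
                  as.numeric(meta$larmor_mhz %||% NA),
                  meta$experiment %||% "unknown",
                  as.numeric(meta$field_tesla %||% NA))
}

#' Write / read a peak list as CSV
#'
#' Columns: `dim1_ppm` (and `dim2_ppm` for 2D lists), `height`,
#' `fwhm_hz`, `integral`, `assignment`; absent quantities are NA.
#'
#' @param peaks Data frame from [pick_peaks_1d()] / [pick_peaks_2d()],
#'   optionally augmented with `fwhm_hz`, `integral`, `assignment`.
#' @param path CSV path.
#' @return The path (write) or a data frame (read).
#' @export
write_peaklist <- function(peaks, path) {
  out <- data.frame(
    dim1_ppm = peaks[["ppm"]] %||% peaks[["ppm_direct"]],
    height = peaks[["height"]],
    fwhm_hz = peaks[["fwhm_hz"]] %||% NA_real_,
    integral = peaks[["integral"]] %||% NA_real_,
    assignment = peaks[["assignment"]] %||% NA_character_
  )
  if (!is.null(peaks[["ppm_indirect"]]))
    out <- cbind(out[1], dim2_ppm = peaks[["ppm_indirect"]], out[-1])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peaklist
#' @export
read_peaklist <- function(path) utils::read.csv(path)

#' Write / read a relaxation series as CSV (`delay_s`, `intensity`)
#'
#' @param series A `relaxation_series`.
#' @param path CSV path.
#' @return The path (write) or a `relaxation_series` (read).
#' @export
write_relaxation_series <- function(series, path) {
  utils::write.csv(data.frame(delay_s = series$delay_s,
                              intensity = series$intensity),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_relaxation_series
#' @param experiment Experiment kind recorded on read.
#' @export
read_relaxation_series <- function(path, experiment = "T1rho_H") {
  df <- utils::read.csv(path)
  structure(list(experiment = experiment, delay_s = df$delay_s,
                 intensity = df$intensity, true_T_s = NA_real_,
                 noise_sigma = NA_real_, seed = NA_integer_),
            class = "relaxation_series")
}
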