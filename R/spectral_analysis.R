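# Quantitative observables from 1D/2D spectra: peak picking with sub-grid
# apex refinement, FWHM measurement by interpolated half-height crossings,
# baseline-corrected region integration, 2D slicing, and nearest-prediction
# cross-peak matching.

# robust noise floor: scaled median absolute deviation
.noise_floor <- function(values) stats::mad(values, constant = 1.4826)

#' Pick peaks in a 1D spectrum
#'
#' Local maxima whose height exceeds `snr_threshold` times the noise floor
#' (median absolute deviation x 1.4826, over `noise_region` if given, else
#' the whole spectrum).  Apex position and height are refined by a 3-point
#' parabola through the apex triplet.
#'
#' @param spectrum A `spectrum1d`.
#' @param snr_threshold Minimum signal-to-noise ratio (default 3).
#' @param noise_region Optional ppm interval known to be signal-free, used
#'   for the noise estimate.
#' @param min_rel_height Minimum peak height as a fraction of the spectrum
#'   maximum (default 0.01); guards against picking lineshape-tail ripples
#'   in effectively noiseless spectra.
#' @return Data frame (`ppm`, `height`, `snr`, `index`) in descending-ppm
#'   order; empty for an all-flat spectrum.
#' @export
pick_peaks_1d <- function(spectrum, snr_threshold = 3, noise_region = NULL,
                          min_rel_height = 0.01) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  y <- spectrum$intensity
  x <- spectrum$ppm
  if (length(y) < 3L || all(y == y[1]))
    return(data.frame(ppm = numeric(0), height = numeric(0),
                      snr = numeric(0), index = integer(0)))
  noise_vals <- if (!is.null(noise_region)) {
    sel <- x >= min(noise_region) & x <= max(noise_region)
    if (!any(sel)) stop("'noise_region' outside the spectrum axis")
    y[sel]
  } else y
  noise <- .noise_floor(noise_vals)
  floor_h <- max(if (noise > 0) snr_threshold * noise else 0,
                 min_rel_height * max(y))

  i <- 2:(length(y) - 1L)
  is_max <- y[i] > y[i - 1L] & y[i] >= y[i + 1L] & y[i] > floor_h
  idx <- i[is_max]
  if (!length(idx))
    return(data.frame(ppm = numeric(0), height = numeric(0),
                      snr = numeric(0), index = integer(0)))
  # parabolic apex refinement (uniform grid)
  ym <- y[idx - 1L]; y0 <- y[idx]; yp <- y[idx + 1L]
  denom <- ym - 2 * y0 + yp
  delta <- ifelse(denom != 0, 0.5 * (ym - yp) / denom, 0)
  step <- x[2] - x[1]  # negative for descending axis
  ppm <- x[idx] + delta * step
  height <- y0 - 0.25 * (ym - yp) * delta
  ord <- order(ppm, decreasing = TRUE)
  data.frame(ppm = ppm[ord], height = height[ord],
             snr = if (noise > 0) height[ord] / noise else Inf,
             index = idx[ord])
}

#' Pick peaks in a 2D spectrum
#'
#' Local maxima of the intensity matrix over the 8-connected
#' neighbourhood, above `snr_threshold` times the matrix noise floor, with
#' per-axis parabolic refinement.
#'
#' @param spectrum A `spectrum2d`.
#' @param snr_threshold Minimum signal-to-noise ratio.
#' @param min_rel_height Minimum peak height as a fraction of the matrix
#'   maximum (default 0.01).
#' @return Data frame (`ppm_direct`, `ppm_indirect`, `height`).
#' @export
pick_peaks_2d <- function(spectrum, snr_threshold = 3, min_rel_height = 0.01) {
  stopifnot(inherits(spectrum, "spectrum2d"))
  m <- spectrum$intensity
  noise <- .noise_floor(as.vector(m))
  floor_h <- max(if (noise > 0) snr_threshold * noise else 0,
                 min_rel_height * max(m))
  nr <- nrow(m); nc <- ncol(m)
  out <- list()
  core <- m[2:(nr - 1L), 2:(nc - 1L)]
  ismax <- core > floor_h
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    shifted <- m[(2 + dr):(nr - 1L + dr), (2 + dc):(nc - 1L + dc)]
    cmp <- if (dr > 0 || (dr == 0 && dc > 0)) core >= shifted else core > shifted
    ismax <- ismax & cmp
  }
  hits <- which(ismax, arr.ind = TRUE)
  if (!nrow(hits))
    return(data.frame(ppm_direct = numeric(0), ppm_indirect = numeric(0),
                      height = numeric(0)))
  ri <- hits[, 1] + 1L; ci <- hits[, 2] + 1L
  refine <- function(axis, vm, v0, vp, i0) {
    denom <- vm - 2 * v0 + vp
    delta <- ifelse(denom != 0, 0.5 * (vm - vp) / denom, 0)
    axis[i0] + delta * (axis[2] - axis[1])
  }
  ppm_i <- refine(spectrum$ppm_indirect, m[cbind(ri - 1L, ci)],
                  m[cbind(ri, ci)], m[cbind(ri + 1L, ci)], ri)
  ppm_d <- refine(spectrum$ppm_direct, m[cbind(ri, ci - 1L)],
                  m[cbind(ri, ci)], m[cbind(ri, ci + 1L)], ci)
  data.frame(ppm_direct = ppm_d, ppm_indirect = ppm_i,
             height = m[cbind(ri, ci)])
}

#' Measure a peak's full width at half maximum
#'
#' Walks outward from the apex to the first crossings below half maximum,
#' interpolates the crossing positions linearly, and converts the ppm
#' width to Hz with the spectrum's Larmor frequency.
#'
#' @param spectrum A `spectrum1d`.
#' @param peak_ppm Apex position (e.g. from [pick_peaks_1d()]).
#' @return FWHM in Hz.
#' @export
measure_fwhm <- function(spectrum, peak_ppm) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  x <- spectrum$ppm; y <- spectrum$intensity
  apex <- which.min(abs(x - peak_ppm))
  # climb to the true local apex in case peak_ppm is slightly off-grid
  while (apex > 1L && y[apex - 1L] > y[apex]) apex <- apex - 1L
  while (apex < length(y) && y[apex + 1L] > y[apex]) apex <- apex + 1L
  half <- y[apex] / 2
  cross <- function(dir) {
    j <- apex
    repeat {
      k <- j + dir
      if (k < 1L || k > length(y))
        stop("half-height crossing not bracketed by the grid; ",
             "an overlapping neighbour may require deconvolution")
      if (y[k] < half) {
        frac <- (y[j] - half) / (y[j] - y[k])
        return(x[j] + frac * (x[k] - x[j]))
      }
      if (y[k] > y[j] && y[k] > y[apex])
        stop("rising flank before half-height crossing; ",
             "an overlapping neighbour may require deconvolution")
      j <- k
    }
  }
  width_ppm <- abs(cross(-1L) - cross(1L))
  ppm_to_hz(width_ppm, spectrum$larmor_mhz)
}

#' Integrate a spectral region with local linear baseline
#'
#' Trapezoidal integral over the window after subtracting the straight
#' line through the intensities at the window edges.
#'
#' @param spectrum A `spectrum1d`.
#' @param window Length-2 ppm interval.
#' @param baseline `"linear"` (default) or `"none"`.
#' @return Integral in intensity x ppm units.
#' @export
integrate_region <- function(spectrum, window, baseline = c("linear", "none")) {
  stopifnot(inherits(spectrum, "spectrum1d"))
  baseline <- match.arg(baseline)
  if (length(window) != 2L || diff(range(window)) == 0)
    stop("'window' must be a non-empty ppm interval")
  sel <- spectrum$ppm >= min(window) & spectrum$ppm <= max(window)
  if (sum(sel) < 2L) stop("window contains fewer than 2 grid points")
  x <- rev(spectrum$ppm[sel])        # ascending for integration
  y <- rev(spectrum$intensity[sel])
  if (baseline == "linear") {
    slope <- (y[length(y)] - y[1]) / (x[length(x)] - x[1])
    y <- y - (y[1] + slope * (x - x[1]))
  }
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Extract a 1D slice from a 2D spectrum
#'
#' Sums intensity rows whose indirect-dimension position lies within
#' `bandwidth` around `at`, returning a direct-dimension `spectrum1d` with
#' inherited metadata.
#'
#' @param spectrum A `spectrum2d`.
#' @param at Indirect-dimension position (ppm).
#' @param bandwidth Full width of the slice band in ppm (> 0).
#' @return A `spectrum1d` over the direct axis.
#' @export
slice_2d <- function(spectrum, at, bandwidth = 0.5) {
  stopifnot(inherits(spectrum, "spectrum2d"))
  if (bandwidth <= 0) stop("'bandwidth' must be positive")
  ax <- spectrum$ppm_indirect
  if (at < min(ax) || at > max(ax)) stop("'at' outside the indirect axis")
  rows <- which(ax >= at - bandwidth / 2 & ax <= at + bandwidth / 2)
  if (!length(rows)) rows <- which.min(abs(ax - at))
  intensity <- if (length(rows) == 1L) spectrum$intensity[rows, ]
               else colSums(spectrum$intensity[rows, , drop = FALSE])
  .new_spectrum1d(spectrum$ppm_direct, intensity, spectrum$nucleus_direct,
                  spectrum$larmor_direct_mhz,
                  paste0(spectrum$experiment, "_slice"),
                  spectrum$field_tesla)
}

#' Match picked peaks to predicted component positions
#'
#' Greedy nearest-neighbour matching in Euclidean ppm distance: candidate
#' (prediction, peak) pairs are visited in order of increasing distance
#' (ties broken in favour of the higher peak), and each prediction and
#' each peak is used at most once.
#'
#' @param peaks Data frame of picked peaks; position columns are all
#'   numeric columns except `height`/`snr`/`index`.
#' @param predicted Data frame with a `label` column and the same number
#'   of position columns as `peaks`.
#' @param tolerance Maximum distance (ppm) for a match to count as within
#'   tolerance (> 0).
#' @return Data frame, one row per prediction: `label`, `distance`,
#'   `within_tolerance`, `peak_row` (row index into `peaks`, NA when no
#'   peak was available).  Unmatched peak rows are in
#'   `attr(, "unmatched_peaks")`.
#' @export
match_cross_peaks <- function(peaks, predicted, tolerance = 0.3) {
  if (tolerance <= 0) stop("'tolerance' must be positive")
  pos_cols <- function(df) setdiff(names(df)[vapply(df, is.numeric, TRUE)],
                                   c("height", "snr", "index"))
  pc <- pos_cols(peaks); qc <- pos_cols(predicted)
  if (length(pc) != length(qc))
    stop("peaks and predictions have different dimensionality")
  n_pk <- nrow(peaks); n_pr <- nrow(predicted)
  res <- data.frame(label = predicted$label, distance = NA_real_,
                    within_tolerance = FALSE, peak_row = NA_integer_)
  if (n_pk && n_pr) {
    pkm <- as.matrix(peaks[, pc, drop = FALSE])
    prm <- as.matrix(predicted[, qc, drop = FALSE])
    dists <- sqrt(outer(rowSums(prm^2), rowSums(pkm^2), "+") -
                    2 * prm %*% t(pkm))
    hgt <- if ("height" %in% names(peaks)) peaks$height else rep(0, n_pk)
    cand <- expand.grid(pred = seq_len(n_pr), peak = seq_len(n_pk))
    cand$d <- dists[cbind(cand$pred, cand$peak)]
    cand <- cand[order(cand$d, -hgt[cand$peak]), ]
    used_pk <- logical(n_pk); used_pr <- logical(n_pr)
    for (r in seq_len(nrow(cand))) {
      p <- cand$pred[r]; k <- cand$peak[r]
      if (used_pr[p] || used_pk[k]) next
      used_pr[p] <- TRUE; used_pk[k] <- TRUE
      res$distance[p] <- cand$d[r]
      res$within_tolerance[p] <- cand$d[r] <= tolerance
      res$peak_row[p] <- k
    }
    attr(res, "unmatched_peaks") <- which(!used_pk)
  } else {
    attr(res, "unmatched_peaks") <- seq_len(n_pk)
  }
  res
}
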