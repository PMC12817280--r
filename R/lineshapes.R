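# Pseudo-Voigt lineshapes with the additive width convention: a line with
# homogeneous (Lorentzian) width H and inhomogeneous width I is modelled as
# a unit-area pseudo-Voigt of TOTAL FWHM F = H + I and Lorentzian mixing
# fraction eta = H / F.  Both mixture members share the same FWHM, so the
# FWHM of the mixture is exactly F and total = homogeneous + inhomogeneous
# holds by construction — mirroring the arithmetic of subtracting the
# homogeneous from the total linewidth to obtain the inhomogeneous part.

#' Unit-area pseudo-Voigt profile
#'
#' @param x Evaluation points (ppm).
#' @param center Line position (ppm).
#' @param fwhm Total full width at half maximum (ppm, > 0).
#' @param eta Lorentzian fraction in \[0, 1\].
#' @return Density values; integrates to 1 over the real line.
#' @export
pseudo_voigt <- function(x, center, fwhm, eta) {
  stopifnot(fwhm > 0, eta >= 0, eta <= 1)
  u <- x - center
  lor <- (2 / (pi * fwhm)) / (1 + (2 * u / fwhm)^2)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  gau <- stats::dnorm(u, sd = sigma)
  eta * lor + (1 - eta) * gau
}

# total FWHM and mixing fraction from the additive convention
.pv_params <- function(homogeneous_hz, inhomogeneous_hz, larmor_mhz) {
  total_hz <- homogeneous_hz + inhomogeneous_hz
  if (total_hz <= 0) stop("total linewidth must be positive")
  list(fwhm_ppm = total_hz / larmor_mhz,
       eta = homogeneous_hz / total_hz)
}
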