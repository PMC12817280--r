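# Unit conversions between the ppm scale and Hz, and Larmor frequencies
# from static field strength via the IUPAC frequency-ratio convention.

# gyromagnetic ratio of 1H over 2*pi, MHz/T; IUPAC Xi ratios relative to 1H
.GAMMA_1H_MHZ_PER_T <- 42.577478518
.IUPAC_XI <- c("1H" = 1.0, "13C" = 0.25144953, "15N" = 0.10132912)

#' Larmor frequency of a nucleus at a given static field
#'
#' Uses the IUPAC unified-scale frequency ratios (Xi) relative to \eqn{^1}H,
#' so 16.4 T gives a ~700 MHz class instrument for \eqn{^1}H and ~175.6 MHz
#' for \eqn{^{13}}C.
#'
#' @param field_tesla Static magnetic field in Tesla (> 0).
#' @param nucleus One of `"1H"`, `"13C"`, `"15N"`.
#' @return Larmor frequency in MHz.
#' @examples
#' larmor_frequency(16.4, "13C")
#' @export
larmor_frequency <- function(field_tesla, nucleus = "13C") {
  if (!is.numeric(field_tesla) || length(field_tesla) != 1L || field_tesla <= 0)
    stop("'field_tesla' must be a single positive number")
  nucleus <- match.arg(nucleus, names(.IUPAC_XI))
  .GAMMA_1H_MHZ_PER_T * field_tesla * unname(.IUPAC_XI[nucleus])
}

#' Convert a chemical-shift difference in ppm to Hz (and back)
#'
#' @param delta_ppm Shift difference in ppm.
#' @param larmor_mhz Larmor frequency of the observed nucleus in MHz (> 0).
#' @return `ppm_to_hz`: the difference in Hz; `hz_to_ppm`: in ppm.
#' @examples
#' ppm_to_hz(1.0, 176.0)  # 176 Hz
#' @export
ppm_to_hz <- function(delta_ppm, larmor_mhz) {
  if (!is.numeric(larmor_mhz) || any(larmor_mhz <= 0))
    stop("'larmor_mhz' must be positive")
  delta_ppm * larmor_mhz
}

#' @rdname ppm_to_hz
#' @param delta_hz Shift difference in Hz.
#' @export
hz_to_ppm <- function(delta_hz, larmor_mhz) {
  if (!is.numeric(larmor_mhz) || any(larmor_mhz <= 0))
    stop("'larmor_mhz' must be positive")
  delta_hz / larmor_mhz
}
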