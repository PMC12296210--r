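#' Physical constants and reference susceptibilities
#'
#' Single source of truth for the constants used throughout the package.
#' Volume magnetic susceptibilities are quoted in ppm (SI volume
#' susceptibility multiplied by 1e6); they are negative for diamagnetic
#' media such as water and glass and positive for paramagnetic media.
#'
#' @return A named list with components
#'   \describe{
#'     \item{mu0}{vacuum permeability, 4\eqn{\pi}e-7 H/m}
#'     \item{gamma_1h_mhz_t}{proton gyromagnetic ratio \eqn{\gamma/2\pi}
#'       in MHz/T}
#'     \item{chi_h2o}{volume susceptibility of H2O, ppm (adopted
#'       literature anchor)}
#'     \item{chi_d2o}{volume susceptibility of D2O, ppm}
#'     \item{chi_air}{volume susceptibility of air, ppm}
#'     \item{spectrometer_mhz}{default 1H spectrometer frequency, MHz}
#'   }
#' @examples
#' nmr_constants()$chi_h2o
#' @export
nmr_constants <- function() {
  list(
    mu0 = 4 * pi * 1e-7,
    gamma_1h_mhz_t = 42.577,
    chi_h2o = -9.05,
    chi_d2o = -9.01,
    chi_air = 0.36,
    spectrometer_mhz = 600.13
  )
}

#' Reference susceptibilities (ppm)
#'
#' Convenience accessors for the reference volume susceptibilities of
#' water, heavy water and air.
#'
#' @return A length-1 numeric, in ppm.
#' @examples
#' chi_d2o()
#' @export
chi_h2o <- function() nmr_constants()$chi_h2o

#' @rdname chi_h2o
#' @export
chi_d2o <- function() nmr_constants()$chi_d2o

#' @rdname chi_h2o
#' @export
chi_air <- function() nmr_constants()$chi_air

#' Convert a frequency shift between Hz and ppm
#'
#' @param shift_hz Shift in Hz.
#' @param shift_ppm Shift in ppm.
#' @param spectrometer_mhz Spectrometer (1H carrier) frequency in MHz.
#'
#' @return Numeric vector of shifts in the target unit.
#' @examples
#' hz_to_ppm(117, 600.13)
#' ppm_to_hz(-0.195, 600.13)
#' @export
hz_to_ppm <- function(shift_hz, spectrometer_mhz = nmr_constants()$spectrometer_mhz) {
  stopifnot(is.numeric(shift_hz), is.numeric(spectrometer_mhz), all(spectrometer_mhz > 0))
  shift_hz / spectrometer_mhz
}

#' @rdname hz_to_ppm
#' @export
ppm_to_hz <- function(shift_ppm, spectrometer_mhz = nmr_constants()$spectrometer_mhz) {
  stopifnot(is.numeric(shift_ppm), is.numeric(spectrometer_mhz), all(spectrometer_mhz > 0))
  shift_ppm * spectrometer_mhz
}
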