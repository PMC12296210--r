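# Susceptibility extraction calculus: interface 2x rule, isotope and
# mixture corrections, NaCl dependence.

#' Fraction-weighted mixture susceptibility
#'
#' Volume susceptibility of a mixture as the fraction-weighted mean of
#' its components, e.g. the reference chi of a 97% D2O / 3% H2O solvent.
#'
#' @param components Data frame with columns `fraction` and `chi`
#'   (ppm). Fractions must be non-negative and sum to 1.
#' @param tol Tolerance on the fraction sum.
#' @return Mixture susceptibility in ppm.
#' @examples
#' mixture_chi(data.frame(fraction = c(0.97, 0.03),
#'                        chi = c(chi_d2o(), chi_h2o())))
#' @export
mixture_chi <- function(components, tol = 1e-8) {
  stopifnot(is.data.frame(components),
            all(c("fraction", "chi") %in% names(components)))
  f <- components$fraction
  if (any(f < 0)) stop("component fractions must be non-negative")
  if (abs(sum(f) - 1) > tol) {
    stop("component fractions must sum to 1 (got ", sum(f), ")")
  }
  sum(f * components$chi)
}

#' Solid susceptibility from a slice-selected interface shift
#'
#' At a flat interface orthogonal to B0 the observed solvent frequency
#' is the flux-conservation average of the two media, so the interface
#' peak sits `(chi_solid - chi_solvent)/2` ppm away from the bulk
#' solvent peak. Inverting:
#' \deqn{\chi_{solid} = \chi_{solvent} + 2\,\Delta\delta,}
#' with `delta = interface peak - bulk peak` in ppm (an upfield
#' interface shoulder gives a negative delta and a solid more
#' diamagnetic than the solvent).
#'
#' @param delta_ppm Interface-minus-bulk peak difference (ppm).
#' @param chi_solvent Solvent reference susceptibility (ppm), e.g. from
#'   [mixture_chi()].
#' @return Solid susceptibility in ppm (unrounded).
#' @examples
#' chi_from_interface_shift(-0.195, -9.0104)  # printed resin
#' @export
chi_from_interface_shift <- function(delta_ppm, chi_solvent) {
  stopifnot(is.numeric(delta_ppm), is.numeric(chi_solvent))
  chi_solvent + 2 * delta_ppm
}

#' Isotope susceptibility difference from paired interface shifts
#'
#' Difference in volume susceptibility between two isotopologue
#' solvents (e.g. H2O vs D2O) obtained from the difference of their
#' interface-shoulder shifts against the same solid, corrected for the
#' samples not being fully protonated/deuterated:
#' \deqn{\Delta\chi = 2\,\Delta\delta / s,}
#' where `s` is the protonation-fraction span between the two samples
#' (0.97 - 0.03 = 0.94 for a 97%/3% pair).
#'
#' @param shift_diff_ppm Difference of the two interface shifts (ppm).
#' @param fraction_span Span in (0, 1].
#' @return Susceptibility difference in ppm.
#' @examples
#' isotope_chi_difference(0.0183, 0.94)
#' @export
isotope_chi_difference <- function(shift_diff_ppm, fraction_span) {
  stopifnot(is.numeric(shift_diff_ppm))
  if (!(fraction_span > 0 && fraction_span <= 1)) {
    stop("fraction_span must be in (0, 1]")
  }
  2 * shift_diff_ppm / fraction_span
}

#' NaCl dependence of water susceptibility
#'
#' Linear model for the volume susceptibility of water as a function of
#' NaCl molarity: slope 0.2 ppm/M with intercept -9.01 ppm (D2O) or
#' -9.05 ppm (H2O), calibrated over 0-2 M. Concentrations above 2 M are
#' extrapolations and warn.
#'
#' @param concentration NaCl concentration in mol/L, >= 0.
#' @param solvent `"D2O"` or `"H2O"`.
#' @return Susceptibility in ppm.
#' @examples
#' salt_chi(2, "H2O")
#' salt_chi(0, "D2O")
#' @export
salt_chi <- function(concentration, solvent = c("D2O", "H2O")) {
  solvent <- match.arg(solvent)
  stopifnot(is.numeric(concentration))
  if (any(concentration < 0)) stop("NaCl concentration must be non-negative")
  if (any(concentration > 2)) {
    warning("salt_chi() calibrated for 0-2 M; extrapolating", call. = FALSE)
  }
  intercept <- if (solvent == "D2O") chi_d2o() else chi_h2o()
  concentration * 0.2 + intercept
}
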