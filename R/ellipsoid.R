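# Closed-form magnetostatics: planar-interface limit and ellipsoid
# demagnetizing factors.

#' On-axis offset above a flat susceptibility interface
#'
#' Closed-form macroscopic offset on the axis of a cylindrical sample at
#' height `h` above a flat interface between a lower medium (chi_lower,
#' e.g. glass or resin) and an upper medium (chi_upper, the solvent),
#' relative to the offset far above the interface. Derived from the
#' equivalent semi-infinite-solenoid field of the uniformly magnetized
#' lower column:
#' \deqn{\delta(h) = \frac{\chi_{lower}-\chi_{upper}}{2}
#'       \left(1 - \frac{h}{\sqrt{h^2+R^2}}\right).}
#' At `h = 0` this is half the susceptibility difference (the flux-
#' conservation interface average) and it decays to 0 for `h >> R`.
#'
#' @param chi_lower,chi_upper Volume susceptibilities (ppm).
#' @param h Height above the interface (mm), >= 0 (the field inside the
#'   lower, solid medium is not modelled).
#' @param radius Cylinder (tube bore) radius R in mm, > 0.
#' @return Offset in ppm relative to the far-field solvent value.
#' @examples
#' interface_offset_on_axis(-9.075, -9.011, h = 0, radius = 2.1)
#' @export
interface_offset_on_axis <- function(chi_lower, chi_upper, h, radius) {
  stopifnot(all(h >= 0), radius > 0)
  (chi_lower - chi_upper) / 2 * (1 - h / sqrt(h^2 + radius^2))
}

demag_axis_integral <- function(a, b, c) {
  # N along the axis with semi-axis c, general triaxial ellipsoid:
  # N_c = (a b c / 2) Int_0^inf ds / ((s + c^2)^{3/2} sqrt((s+a^2)(s+b^2)))
  f <- function(s) 1 / ((s + c^2)^1.5 * sqrt((s + a^2) * (s + b^2)))
  # substitution s = c^2 t/(1-t) maps [0,Inf) to [0,1) and tames the tail
  gfun <- function(t) {
    s <- c^2 * t / (1 - t)
    f(s) * c^2 / (1 - t)^2
  }
  (a * b * c / 2) * stats::integrate(gfun, 0, 1, rel.tol = 1e-12,
                                     abs.tol = 1e-14)$value
}

#' Demagnetizing factors of a general ellipsoid
#'
#' Demagnetizing factors (N_a, N_b, N_c) for a uniformly magnetized
#' ellipsoid with semi-axes a, b, c. Closed elliptic forms are used for
#' spheres and spheroids (prolate: \eqn{N_c = ((1-e^2)/e^3)(\mathrm{atanh}\,e - e)}
#' with \eqn{e^2 = 1 - a^2/c^2}; oblate analogue with \eqn{\arcsin}),
#' and the standard elliptic-integral quadrature for triaxial shapes.
#' The factors always satisfy N_a + N_b + N_c = 1.
#'
#' @param a,b,c Semi-axes in mm, all > 0. `c` is the axis conventionally
#'   aligned with B0.
#' @return Named numeric vector `c(N_a, N_b, N_c)`.
#' @examples
#' demagnetizing_factors(1, 1, 1)              # sphere: 1/3 each
#' demagnetizing_factors(1.65, 1.65, 11.5)[3]  # prolate microcell, N_c
#' @export
demagnetizing_factors <- function(a, b, c) {
  stopifnot(a > 0, b > 0, c > 0)
  rel <- function(u, v) abs(u - v) <= 1e-12 * max(u, v)
  if (rel(a, b) && rel(b, c)) {
    out <- c(1, 1, 1) / 3
  } else if (rel(a, b)) {
    if (c > a) {  # prolate, long axis c
      e <- sqrt(1 - (a / c)^2)
      nc <- ((1 - e^2) / e^3) * (atanh(e) - e)
    } else {      # oblate, short axis c
      e <- sqrt(1 - (c / a)^2)
      nc <- (1 / e^2) * (1 - sqrt(1 - e^2) / e * asin(e))
    }
    out <- c((1 - nc) / 2, (1 - nc) / 2, nc)
  } else {
    out <- c(demag_axis_integral(b, c, a),
             demag_axis_integral(a, c, b),
             demag_axis_integral(a, b, c))
    out <- out / sum(out)  # renormalize quadrature residual (~1e-12)
  }
  names(out) <- c("N_a", "N_b", "N_c")
  out
}

#' Uniform interior offset of an ellipsoidal cavity
#'
#' Nuclear (Lorentz-corrected) offset inside an ellipsoid of
#' susceptibility `chi_in` embedded in a medium `chi_out`, relative to a
#' same-material reference far outside: `(1/3 - N_c) * (chi_in -
#' chi_out)` with the long axis c parallel to B0. The interior field is
#' uniform, and exactly zero for a sphere regardless of the mismatch --
#' the property that makes ellipsoidal sample cells insensitive to
#' solvent/resin susceptibility mismatch.
#'
#' @param chi_in,chi_out Susceptibilities (ppm).
#' @param semi_axes `c(a, b, c)` in mm; `c` (third) is along B0.
#' @return Offset in ppm.
#' @examples
#' ellipsoid_interior_offset(-9.011, -9.40, c(1.65, 1.65, 11.5))
#' @export
ellipsoid_interior_offset <- function(chi_in, chi_out, semi_axes) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0))
  nfac <- demagnetizing_factors(semi_axes[1], semi_axes[2], semi_axes[3])
  (1 / 3 - nfac[["N_c"]]) * (chi_in - chi_out)
}
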