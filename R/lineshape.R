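# Line-shape simulation: solvent-voxel offset histograms under coil and
# slice weighting, Lorentzian convolution, and diagnostic widths.

#' Receiver-coil sensitivity profile
#'
#' Flat window with raised-cosine roll-off, symmetric about the coil
#' center. The true profile of a probe is not modelled; this is a
#' configurable stand-in for a finite sensitive window.
#'
#' @param center Coil center height (mm).
#' @param flat_length Length of the fully sensitive window (mm).
#' @param rolloff Raised-cosine roll-off length on each side (mm).
#' @return Object of class `coil_profile`.
#' @export
coil_profile <- function(center = 5, flat_length = 16, rolloff = 2) {
  stopifnot(flat_length > 0, rolloff >= 0)
  structure(list(center = center, flat_length = flat_length, rolloff = rolloff),
            class = "coil_profile")
}

#' @rdname coil_profile
#' @param coil A `coil_profile`.
#' @param z Heights (mm).
#' @return Weights in `[0, 1]`.
#' @export
coil_weight <- function(coil, z) {
  stopifnot(inherits(coil, "coil_profile"))
  d <- abs(z - coil$center) - coil$flat_length / 2
  w <- numeric(length(z))
  w[d <= 0] <- 1
  if (coil$rolloff > 0) {
    ramp <- d > 0 & d < coil$rolloff
    w[ramp] <- 0.5 * (1 + cos(pi * d[ramp] / coil$rolloff))
  }
  w
}

#' Slice-selection excitation profile
#'
#' @param center Slice center height h (mm).
#' @param thickness Slice thickness (mm), > 0. For the rectangular
#'   window the profile integrates to the thickness; the Gaussian window
#'   uses `thickness` as its FWHM and is normalized to the same
#'   integral.
#' @param window `"rectangular"` (ideal selection) or `"gaussian"`.
#' @return Object of class `slice_profile`.
#' @export
slice_profile <- function(center, thickness = 0.6,
                          window = c("rectangular", "gaussian")) {
  stopifnot(thickness > 0)
  window <- match.arg(window)
  structure(list(center = center, thickness = thickness, window = window),
            class = "slice_profile")
}

#' @rdname slice_profile
#' @param slice A `slice_profile`.
#' @param z Heights (mm).
#' @return Weights in `[0, 1]` (rectangular) or a Gaussian with unit
#'   peak and matching integral.
#' @export
slice_weight <- function(slice, z) {
  stopifnot(inherits(slice, "slice_profile"))
  if (slice$window == "rectangular") {
    # tolerance keeps voxel centers that land on the slab edge inside,
    # regardless of floating-point representation of the grid coordinates
    eps <- 1e-9 * (abs(slice$center) + slice$thickness)
    as.numeric(abs(z - slice$center) <= slice$thickness / 2 + eps)
  } else {
    sd <- slice$thickness / (2 * sqrt(2 * log(2)))
    exp(-(z - slice$center)^2 / (2 * sd^2)) * slice$thickness /
      (sd * sqrt(2 * pi))
  }
}

#' Solvent weight map
#'
#' Identifies solvent voxels (chi within `chi_tol` of `solvent_chi`) and
#' multiplies coil and slice weights evaluated at each voxel's height.
#'
#' @param chi_map A `susceptibility_map`.
#' @param solvent_chi Solvent susceptibility (ppm).
#' @param coil Optional [coil_profile()].
#' @param slice Optional [slice_profile()].
#' @param chi_tol Matching tolerance in ppm. Supersampled boundary
#'   voxels hold mixed chi values and are excluded by a tight tolerance.
#' @return List with `grid` and 3-D array `weight`.
#' @export
solvent_weight_map <- function(chi_map, solvent_chi, coil = NULL, slice = NULL,
                               chi_tol = 1e-6) {
  stopifnot(inherits(chi_map, "susceptibility_map"))
  w <- array(as.numeric(abs(chi_map$chi - solvent_chi) <= chi_tol),
             chi_map$grid$counts)
  if (!any(w > 0)) stop("no solvent voxels match solvent_chi within chi_tol")
  zw <- rep(1, chi_map$grid$counts[3])
  if (!is.null(coil)) zw <- zw * coil_weight(coil, chi_map$grid$z)
  if (!is.null(slice)) zw <- zw * slice_weight(slice, chi_map$grid$z)
  w <- sweep(w, 3, zw, `*`)
  list(grid = chi_map$grid, weight = w)
}

#' Simulate a solvent spectrum from a field map
#'
#' Histograms the nuclear offsets of solvent voxels, weighted by the
#' coil-sensitivity and slice-selection profiles, and convolves the
#' stick histogram with a Lorentzian of the given full width at half
#' maximum. The convolution kernel is renormalized to unit sum so total
#' intensity equals total voxel weight exactly.
#'
#' @param field A `field_map`.
#' @param chi_map The matching `susceptibility_map` (used to identify
#'   solvent voxels).
#' @param solvent_chi Solvent susceptibility (ppm).
#' @param coil Optional [coil_profile()].
#' @param slice Optional [slice_profile()]; `NULL` simulates the
#'   whole-sample (non-selective) spectrum.
#' @param linewidth_hz Lorentzian FWHM in Hz (> 0); default 1 Hz, a
#'   typical non-spinning 1H linewidth.
#' @param spectrometer_mhz Spectrometer frequency (MHz) for Hz/ppm
#'   conversion.
#' @param chi_tol Solvent matching tolerance (ppm).
#' @param pad_ppm Extra frequency-axis margin beyond the offset range,
#'   in units of the linewidth (default 10 linewidths each side).
#' @return A tibble of class `nmr_spectrum` with columns `ppm` and
#'   `intensity`; attributes `spectrometer_mhz`, `bin_width_ppm` and
#'   `sticks` (the pre-convolution weighted histogram as a tibble).
#' @export
simulate_spectrum <- function(field, chi_map, solvent_chi, coil = NULL,
                              slice = NULL, linewidth_hz = 1,
                              spectrometer_mhz = nmr_constants()$spectrometer_mhz,
                              chi_tol = 1e-6, pad_ppm = 10) {
  stopifnot(inherits(field, "field_map"), linewidth_hz > 0)
  if (!grid_equal(field$grid, chi_map$grid)) {
    stop("field and chi map are defined on different grids")
  }
  wmap <- solvent_weight_map(chi_map, solvent_chi, coil, slice, chi_tol)
  sel <- wmap$weight > 0
  if (!any(sel)) stop("slice/coil weighting leaves no contributing solvent voxels")
  offs <- field$offset_ppm[sel]
  wts <- wmap$weight[sel]

  lw_ppm <- linewidth_hz / spectrometer_mhz
  bin <- lw_ppm / 4
  lo <- min(offs) - pad_ppm * lw_ppm
  hi <- max(offs) + pad_ppm * lw_ppm
  centers <- seq(lo, hi, by = bin)
  idx <- pmin(pmax(round((offs - lo) / bin) + 1, 1L), length(centers))
  stick <- numeric(length(centers))
  tb <- tapply(wts, idx, sum)
  stick[as.integer(names(tb))] <- tb

  # Lorentzian kernel, truncated symmetrically and renormalized so the
  # convolution conserves total weight
  half_n <- length(centers) - 1L
  kx <- (-half_n:half_n) * bin
  kern <- (lw_ppm / 2)^2 / (kx^2 + (lw_ppm / 2)^2)
  kern <- kern / sum(kern)
  intensity <- as.numeric(stats::convolve(stick, rev(kern), type = "open"))
  intensity <- intensity[(half_n + 1L):(half_n + length(centers))]
  # renormalize the small Lorentzian tail mass lost beyond the frequency
  # window, so the spectrum integral equals the total voxel weight
  intensity <- intensity * (sum(stick) / sum(intensity))

  out <- tibble::tibble(ppm = centers, intensity = intensity)
  class(out) <- c("nmr_spectrum", class(out))
  attr(out, "spectrometer_mhz") <- spectrometer_mhz
  attr(out, "bin_width_ppm") <- bin
  attr(out, "linewidth_hz") <- linewidth_hz
  attr(out, "sticks") <- tibble::tibble(ppm = centers, weight = stick)
  out
}

#' Peak position of a spectrum
#'
#' Frequency (ppm) of maximum intensity. Exact ties are broken toward
#' downfield, i.e. the higher (more positive) offset.
#'
#' @param spec An `nmr_spectrum`.
#' @return Peak position in ppm.
#' @export
peak_position <- function(spec) {
  stopifnot(inherits(spec, "nmr_spectrum"), nrow(spec) > 0)
  mx <- max(spec$intensity)
  max(spec$ppm[spec$intensity >= mx * (1 - 1e-12)])
}

#' Base width of a line shape
#'
#' Width of the frequency support whose (pre-convolution) stick weight
#' exceeds a small fraction of the maximum stick. For a long solvent
#' column above a flat interface the base width approaches half the
#' susceptibility difference between the two media (in ppm).
#'
#' The default threshold, 0.55% of the maximum, follows the convention
#' of quoting solvent-line quality at 0.55% of the peak height. Note
#' that the threshold interacts with the histogram bin width (a quarter
#' linewidth): the bulk-solvent plateau concentrates into few tall bins
#' while interface-shifted spins spread thinly, so thresholds much
#' above 1% read only the plateau and under-report the physical base.
#'
#' @param spec An `nmr_spectrum` from [simulate_spectrum()].
#' @param threshold_fraction Fraction of the maximum (0 < f < 0.5).
#' @return Width in ppm.
#' @export
base_width <- function(spec, threshold_fraction = 0.0055) {
  stopifnot(inherits(spec, "nmr_spectrum"),
            threshold_fraction > 0, threshold_fraction < 0.5)
  sticks <- attr(spec, "sticks")
  if (is.null(sticks) || all(sticks$weight == 0)) {
    stop("spectrum has no stick histogram (or it is all zero)")
  }
  keep <- sticks$weight > threshold_fraction * max(sticks$weight)
  diff(range(sticks$ppm[keep]))
}

#' Slice-selection bandwidth
#'
#' Frequency bandwidth corresponding to a slice of given thickness under
#' a z gradient: `bw = (gamma/2pi) * G * dz`, with G converted from
#' G/cm to T/m and dz from mm to m.
#'
#' @param gradient_g_cm Gradient strength in gauss per cm.
#' @param thickness_mm Slice thickness in mm.
#' @param gamma_mhz_t Gyromagnetic ratio over 2 pi, MHz/T (1H default).
#' @return Bandwidth in Hz.
#' @examples
#' slice_bandwidth(11.5, 0.6)
#' @export
slice_bandwidth <- function(gradient_g_cm, thickness_mm,
                            gamma_mhz_t = nmr_constants()$gamma_1h_mhz_t) {
  stopifnot(gradient_g_cm > 0, thickness_mm >= 0)
  gamma_mhz_t * 1e6 * (gradient_g_cm * 1e-2) * (thickness_mm * 1e-3)
}

#' 1-D density projection of a weight map
#'
#' Sums a solvent/coil weight map over the two axes orthogonal to
#' `axis`, the profile measured by a one-pulse gradient-encoded
#' projection experiment. A sphere projects to the parabolic chord-area
#' profile; the microcell's z projection spans the ellipsoid length.
#'
#' @param weight_map A list with `grid` and `weight` (from
#'   [solvent_weight_map()]) or a `susceptibility_map` (its occupancy is
#'   used directly).
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return A tibble with columns `mm` (voxel-center coordinate) and
#'   `weight`.
#' @export
projection_profile <- function(weight_map, axis = c("z", "x", "y")) {
  axis <- match.arg(axis)
  if (inherits(weight_map, "susceptibility_map")) {
    stop("pass a weight map from solvent_weight_map(), not a raw chi map")
  }
  stopifnot(is.list(weight_map), !is.null(weight_map$grid), !is.null(weight_map$weight))
  ai <- match(axis, c("x", "y", "z"))
  prof <- apply(weight_map$weight, ai, sum)
  tibble::tibble(mm = weight_map$grid[[axis]], weight = as.numeric(prof))
}
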