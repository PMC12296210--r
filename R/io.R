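# File I/O: NIfTI-1 volumes for maps, two-column CSV for spectra, JSON
# for chi reports.

#' Write/read susceptibility and field maps as NIfTI-1 volumes
#'
#' Maps are stored as NIfTI-1 with the grid spacing (mm) in the header
#' pixdim and the world position (mm) of the first voxel center in the
#' qform translation, axes aligned with the grid.
#'
#' @param map A `susceptibility_map` or `field_map`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_map_nifti()` returns the path invisibly;
#'   `read_map_nifti()` returns a list with `grid` and `values`.
#' @export
write_map_nifti <- function(map, path) {
  values <- if (inherits(map, "field_map")) map$offset_ppm else map$chi
  g <- map$grid
  img <- RNifti::asNifti(values)
  affine <- diag(c(g$spacing, 1))
  affine[1:3, 4] <- g$origin
  img <- RNifti::`qform<-`(img, value = structure(affine, code = 2L))
  RNifti::pixdim(img) <- g$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_map_nifti
#' @export
read_map_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  affine <- RNifti::xform(img)
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))  # axis-aligned spacing
  arr <- as.array(img)
  list(grid = voxel_grid(dim(arr), sp, origin = affine[1:3, 4]),
       values = arr)
}

#' Write a spectrum as two-column CSV with JSON metadata sidecar
#'
#' @param spec An `nmr_spectrum`.
#' @param path CSV path; metadata goes to `<path>.json`.
#' @return The CSV path, invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "nmr_spectrum"))
  utils::write.csv(as.data.frame(spec)[, c("ppm", "intensity")], path,
                   row.names = FALSE)
  meta <- list(
    spectrometer_mhz = attr(spec, "spectrometer_mhz"),
    bin_width_ppm = attr(spec, "bin_width_ppm"),
    linewidth_hz = attr(spec, "linewidth_hz"),
    peak_ppm = peak_position(spec),
    total_intensity = sum(spec$intensity)
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- tibble::as_tibble(df)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    attr(out, "spectrometer_mhz") <- meta$spectrometer_mhz
    attr(out, "bin_width_ppm") <- meta$bin_width_ppm
    attr(out, "linewidth_hz") <- meta$linewidth_hz
  }
  class(out) <- c("nmr_spectrum", class(out))
  out
}

#' Susceptibility report
#'
#' Assembles the susceptometry chain for one interface measurement into
#' a reviewable record: inputs, solvent reference, and derived solid
#' susceptibility (reported rounded to 2 decimals in ppm; the unrounded
#' value is included).
#'
#' @param delta Interface-minus-bulk peak difference, in ppm (or Hz,
#'   with `units = "hz"`).
#' @param solvent_components Data frame with `fraction` and `chi`
#'   columns describing the solvent mixture (see [mixture_chi()]).
#' @param units `"ppm"` or `"hz"`.
#' @param spectrometer_mhz Needed when `units = "hz"`.
#' @return A list of class `chi_report`.
#' @examples
#' chi_report(-0.195, data.frame(fraction = c(0.99, 0.01),
#'                               chi = c(chi_d2o(), chi_h2o())))
#' @export
chi_report <- function(delta, solvent_components, units = c("ppm", "hz"),
                       spectrometer_mhz = nmr_constants()$spectrometer_mhz) {
  units <- match.arg(units)
  delta_ppm <- if (units == "hz") hz_to_ppm(delta, spectrometer_mhz) else delta
  chi_solv <- mixture_chi(solvent_components)
  chi_solid <- chi_from_interface_shift(delta_ppm, chi_solv)
  structure(list(
    inputs = list(delta = delta, units = units,
                  spectrometer_mhz = if (units == "hz") spectrometer_mhz else NULL,
                  solvent_components = solvent_components),
    references = list(chi_h2o = chi_h2o(), chi_d2o = chi_d2o()),
    chi_solvent = chi_solv,
    chi_solid = chi_solid,
    chi_solid_reported = round(chi_solid, 2)
  ), class = "chi_report")
}

#' @export
print.chi_report <- function(x, ...) {
  cat("<chi_report>\n")
  cat(sprintf("  delta (interface - bulk): %g %s\n", x$inputs$delta, x$inputs$units))
  cat(sprintf("  solvent reference chi: %.4f ppm\n", x$chi_solvent))
  cat(sprintf("  solid chi: %.4f ppm (reported %.2f ppm)\n",
              x$chi_solid, x$chi_solid_reported))
  invisible(x)
}

#' @rdname chi_report
#' @param report A `chi_report`.
#' @param path Output JSON path.
#' @export
write_chi_report <- function(report, path) {
  stopifnot(inherits(report, "chi_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
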