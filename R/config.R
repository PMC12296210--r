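# Run configuration (YAML) and the batch entry points behind the CLI.

config_fail <- function(path, msg) {
  stop(sprintf("config error at '%s': %s", path, msg), call. = FALSE)
}

#' Read and validate a simulation run configuration
#'
#' Structured YAML with a versioned schema. Required keys: `preset`,
#' `materials` (named chi values in ppm: `solvent`, `solid`, optional
#' `background`), `grid` (`counts`, `spacing`, optional `center`),
#' `seed`. Optional: `spectrometer_mhz`, `linewidth_hz`, `coil`
#' (`center`, `flat_length`, `rolloff`), `slices` (list of `center`,
#' `thickness`), `shimmed`, `supersampling`, `preset_args` (extra
#' [preset_scene()] arguments such as `solvent_height` or
#' `channel_diameter`).
#'
#' @param path YAML file path.
#' @return A validated `run_config` list (with `config_md5` recorded).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) config_fail(path, "file not found")
  cfg <- yaml::read_yaml(path)
  sv <- cfg$schema_version
  if (is.null(sv) || !sv %in% 1) config_fail("schema_version", "must be 1")
  if (is.null(cfg$preset) ||
      !cfg$preset %in% c("shigemi", "plug_in_tube", "microcell")) {
    config_fail("preset", "must be one of shigemi, plug_in_tube, microcell")
  }
  m <- cfg$materials
  if (is.null(m$solvent) || !is.numeric(m$solvent)) {
    config_fail("materials.solvent", "numeric chi (ppm) required")
  }
  if (is.null(m$solid) || !is.numeric(m$solid)) {
    config_fail("materials.solid", "numeric chi (ppm) required")
  }
  g <- cfg$grid
  if (is.null(g$counts) || length(g$counts) != 3 || any(g$counts < 4)) {
    config_fail("grid.counts", "3 integers >= 4 required")
  }
  if (is.null(g$spacing) || !all(unlist(g$spacing) > 0)) {
    config_fail("grid.spacing", "positive spacing (mm) required")
  }
  if (is.null(cfg$seed) || !is.numeric(cfg$seed)) {
    config_fail("seed", "integer seed required")
  }
  for (i in seq_along(cfg$slices)) {
    sl <- cfg$slices[[i]]
    if (is.null(sl$center) || is.null(sl$thickness) || sl$thickness <= 0) {
      config_fail(sprintf("slices[%d]", i), "center and thickness > 0 required")
    }
  }
  cfg$config_md5 <- unname(tools::md5sum(path))
  class(cfg) <- "run_config"
  cfg
}

run_config_scene <- function(cfg) {
  bg <- cfg$materials$background
  if (is.null(bg)) bg <- chi_air()
  args <- c(list(name = cfg$preset,
                 chi_solvent = cfg$materials$solvent,
                 chi_solid = cfg$materials$solid,
                 background_chi = bg),
            cfg$preset_args)
  do.call(preset_scene, args)
}

run_config_grid <- function(cfg) {
  g <- cfg$grid
  sp <- unlist(g$spacing)
  if (length(sp) == 1) sp <- rep(sp, 3)
  center <- if (is.null(g$center)) c(0, 0, 0) else unlist(g$center)
  voxel_grid(unlist(g$counts), sp, center = center)
}

#' Run a field + spectra simulation from a configuration
#'
#' Voxelizes the configured preset scene, solves the forward field
#' (shim-referenced when the preset provides a matched reference),
#' simulates the whole-sample spectrum and one spectrum per configured
#' slice, and writes: susceptibility and field maps (NIfTI-1), spectra
#' (CSV + JSON sidecars) and a JSON summary (peak positions, base
#' width, near-interface/far on-axis offsets, seed, config hash).
#' Deterministic given the seed. Partial outputs are removed on
#' failure.
#'
#' @param cfg A `run_config` from [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The summary list, invisibly.
#' @export
run_simulate <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  set.seed(as.integer(cfg$seed))
  scene <- run_config_scene(cfg)
  grid <- run_config_grid(cfg)
  ss <- if (is.null(cfg$supersampling)) 3 else cfg$supersampling
  shim <- if (is.null(cfg$shimmed)) TRUE else isTRUE(cfg$shimmed)
  aniso <- length(unique(grid$spacing)) > 1
  sim <- simulate_field(scene, grid, supersampling = ss, shimmed = shim,
                        anisotropic = aniso)

  p_chi <- file.path(out_dir, "chi_map.nii.gz")
  p_field <- file.path(out_dir, "field_map.nii.gz")
  write_map_nifti(sim$chi_map, p_chi)
  write_map_nifti(sim$field, p_field)
  written <- c(written, p_chi, p_field)

  mhz <- if (is.null(cfg$spectrometer_mhz)) nmr_constants()$spectrometer_mhz else cfg$spectrometer_mhz
  lw <- if (is.null(cfg$linewidth_hz)) 1 else cfg$linewidth_hz
  coil <- if (is.null(cfg$coil)) coil_profile() else {
    do.call(coil_profile, cfg$coil)
  }

  spectra <- list()
  whole <- simulate_spectrum(sim$field, sim$chi_map, cfg$materials$solvent,
                             coil = coil, linewidth_hz = lw,
                             spectrometer_mhz = mhz)
  p <- file.path(out_dir, "spectrum_whole.csv")
  write_spectrum_csv(whole, p)
  written <- c(written, p, paste0(p, ".json"))
  spectra$whole <- list(file = basename(p), peak_ppm = peak_position(whole),
                        base_width_ppm = base_width(whole))
  for (i in seq_along(cfg$slices)) {
    sl <- cfg$slices[[i]]
    sp <- simulate_spectrum(sim$field, sim$chi_map, cfg$materials$solvent,
                            coil = coil,
                            slice = slice_profile(sl$center, sl$thickness),
                            linewidth_hz = lw, spectrometer_mhz = mhz)
    p <- file.path(out_dir, sprintf("spectrum_slice_h%+.1fmm.csv", sl$center))
    write_spectrum_csv(sp, p)
    written <- c(written, p, paste0(p, ".json"))
    spectra[[sprintf("slice_%d", i)]] <- list(
      file = basename(p), center_mm = sl$center, thickness_mm = sl$thickness,
      peak_ppm = peak_position(sp))
  }

  # on-axis diagnostics: nearest-to-interface and far solvent offsets
  dz <- grid$spacing[3]
  near <- field_at(sim$field, cbind(0, 0, dz / 2))
  far <- field_at(sim$field, cbind(0, 0, 13))
  summary <- list(
    package = "nmrcell",
    seed = as.integer(cfg$seed),
    config_md5 = cfg$config_md5,
    preset = cfg$preset,
    interface_offset_ppm = list(near_axis = near, far_axis_13mm = far,
                                near_minus_far = near - far),
    spectra = spectra
  )
  p_sum <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, p_sum, auto_unbox = TRUE, digits = NA)
  written <- c(written, p_sum)
  ok <- TRUE
  invisible(summary)
}

#' Extract a solid susceptibility from a measurement table
#'
#' Reads a CSV of labelled peak positions (columns: `label`, `h_mm`,
#' and `peak_ppm` or `peak_hz`), takes `delta` = interface peak minus
#' bulk peak, and runs the susceptometry chain (Hz-to-ppm conversion,
#' fraction-weighted solvent reference, 2x interface rule).
#'
#' @param table_path CSV path. Exactly one row labelled `interface` and
#'   one labelled `bulk` are required.
#' @param solvent_components Data frame (`fraction`, `chi`) for the
#'   solvent reference; see [mixture_chi()].
#' @param spectrometer_mhz Used when the table reports Hz.
#' @param out_json Optional path for the JSON chi report.
#' @return A `chi_report`.
#' @export
run_extract <- function(table_path, solvent_components,
                        spectrometer_mhz = nmr_constants()$spectrometer_mhz,
                        out_json = NULL) {
  df <- utils::read.csv(table_path)
  if (!"label" %in% names(df)) stop("measurement table needs a 'label' column")
  unit_col <- intersect(c("peak_ppm", "peak_hz"), names(df))
  if (length(unit_col) != 1) {
    stop("measurement table needs exactly one of 'peak_ppm' or 'peak_hz'")
  }
  pick <- function(lbl) {
    rows <- df[df$label == lbl, , drop = FALSE]
    if (nrow(rows) == 0) stop("missing '", lbl, "' row in measurement table")
    if (nrow(rows) > 1) stop("ambiguous duplicate '", lbl, "' rows")
    rows[[unit_col]]
  }
  delta <- pick("interface") - pick("bulk")
  rep <- chi_report(delta, solvent_components,
                    units = if (unit_col == "peak_hz") "hz" else "ppm",
                    spectrometer_mhz = spectrometer_mhz)
  if (!is.null(out_json)) write_chi_report(rep, out_json)
  rep
}
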