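# Config validation, batch runs, synthetic fixtures, file I/O and CLI.

write_cfg <- function(lines, .env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".yaml", .local_envir = .env)
  writeLines(lines, path)
  path
}

small_cfg <- function(extra = character(0), .env = parent.frame()) {
  write_cfg(c(
    "schema_version: 1",
    "preset: shigemi",
    "materials: {solvent: -9.011, solid: -9.075, background: 0.36}",
    "grid:",
    "  counts: [20, 20, 120]",
    "  spacing: [0.3, 0.3, 0.2]",
    "  center: [0, 0, 7]",
    "seed: 7",
    "preset_args: {solvent_height: 16, solid_length: 5}",
    "slices:",
    "  - {center: 0, thickness: 0.6}",
    "  - {center: 13, thickness: 0.6}",
    extra), .env = .env)
}

test_that("config schema violations are reported with field paths", {
  expect_error(read_run_config(withr::local_tempfile()), "not found")
  p <- write_cfg(c("schema_version: 3", "preset: shigemi"))
  expect_error(read_run_config(p), "schema_version")
  p2 <- write_cfg(c("schema_version: 1", "preset: nonsense"))
  expect_error(read_run_config(p2), "preset")
  p3 <- write_cfg(c("schema_version: 1", "preset: shigemi",
                    "materials: {solvent: -9.011}"))
  expect_error(read_run_config(p3), "materials.solid")
  p4 <- write_cfg(c("schema_version: 1", "preset: shigemi",
                    "materials: {solvent: -9.011, solid: -9.075}",
                    "grid: {counts: [2, 2, 2], spacing: [1, 1, 1]}"))
  expect_error(read_run_config(p4), "grid.counts")
})

test_that("run_simulate writes maps, spectra and a reproducible summary", {
  cfg <- read_run_config(small_cfg())
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  s1 <- run_simulate(cfg, out1)
  s2 <- run_simulate(cfg, out2)
  expect_setequal(
    list.files(out1),
    c("chi_map.nii.gz", "field_map.nii.gz", "spectrum_whole.csv",
      "spectrum_whole.csv.json", "spectrum_slice_h+0.0mm.csv",
      "spectrum_slice_h+0.0mm.csv.json", "spectrum_slice_h+13.0mm.csv",
      "spectrum_slice_h+13.0mm.csv.json", "summary.json"))
  # deterministic rerun: identical numeric outputs
  expect_identical(readLines(file.path(out1, "summary.json")),
                   readLines(file.path(out2, "summary.json")))
  expect_identical(readLines(file.path(out1, "spectrum_whole.csv")),
                   readLines(file.path(out2, "spectrum_whole.csv")))
  expect_equal(s1$seed, 7)
  expect_match(s1$config_md5, "^[0-9a-f]{32}$")
  # the slice at h = 13 mm sits on the bulk peak; the h = 0 slice is upfield
  expect_lt(abs(s1$spectra$slice_2$peak_ppm - s1$spectra$whole$peak_ppm),
            0.002)
  expect_lt(s1$spectra$slice_1$peak_ppm, s1$spectra$whole$peak_ppm - 0.02)
  # maps round-trip through NIfTI with grid metadata intact
  r <- read_map_nifti(file.path(out1, "field_map.nii.gz"))
  expect_equal(r$grid$counts, c(20L, 20L, 120L))
  expect_equal(r$grid$spacing, c(0.3, 0.3, 0.2), tolerance = 1e-6)
  sp <- read_spectrum_csv(file.path(out1, "spectrum_whole.csv"))
  expect_s3_class(sp, "nmr_spectrum")
  expect_equal(peak_position(sp), s1$spectra$whole$peak_ppm, tolerance = 1e-9)
})

test_that("run_extract reproduces the reported solid susceptibilities", {
  tab <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(label = c("interface", "bulk"), h_mm = c(0, 13),
                       peak_ppm = c(-0.195, 0)), tab, row.names = FALSE)
  rep <- run_extract(tab, solvent_99d2o())
  expect_equal(rep$chi_solid_reported, -9.40)
  # same table in Hz
  tab2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(label = c("interface", "bulk"), h_mm = c(0, 13),
                       peak_hz = c(-117, 0)), tab2, row.names = FALSE)
  rep2 <- run_extract(tab2, solvent_99d2o(), spectrometer_mhz = 600.13)
  expect_equal(rep2$chi_solid_reported, -9.40)
  # glass against 97% D2O
  tab3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(label = c("interface", "bulk"), h_mm = c(0, 13),
                       peak_ppm = c(-0.032, 0)), tab3, row.names = FALSE)
  expect_equal(run_extract(tab3, solvent_97d2o())$chi_solid_reported,
               -9.08)
  # matched media: chi_solid equals chi_solvent
  tab4 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(label = c("interface", "bulk"), h_mm = c(0, 13),
                       peak_ppm = c(0, 0)), tab4, row.names = FALSE)
  rep4 <- run_extract(tab4, solvent_99d2o())
  expect_equal(rep4$chi_solid, rep4$chi_solvent)
  # missing and duplicate rows
  tab5 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(label = "bulk", h_mm = 13, peak_ppm = 0), tab5,
            row.names = FALSE)
  expect_error(run_extract(tab5, solvent_99d2o()), "interface")
  tab6 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(label = c("interface", "interface", "bulk"),
                       h_mm = c(0, 0, 13), peak_ppm = c(-0.1, -0.2, 0)),
            tab6, row.names = FALSE)
  expect_error(run_extract(tab6, solvent_99d2o()), "duplicate")
})

test_that("chi reports serialize to JSON", {
  rep <- chi_report(-0.195, solvent_99d2o())
  p <- withr::local_tempfile(fileext = ".json")
  write_chi_report(rep, p)
  back <- jsonlite::read_json(p)
  expect_equal(back$chi_solid_reported, -9.4)
  expect_equal(back$chi_solvent, rep$chi_solvent, tolerance = 1e-12)
})

test_that("synthetic series are reproducible and exact at zero noise", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  generate_synthetic_series(0.2, -9.01, c(0, 0.5, 1, 1.5, 2), 0.01,
                            seed = 11, path = p1)
  generate_synthetic_series(0.2, -9.01, c(0, 0.5, 1, 1.5, 2), 0.01,
                            seed = 11, path = p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_synthetic_series(p1)
  expect_equal(back$x, c(0, 0.5, 1, 1.5, 2))
  expect_match(attr(back, "provenance")[2], "seed: 11")
  exact <- generate_synthetic_series(0.2, -9.01, c(0, 1, 2), 0, seed = 1)
  expect_equal(exact$y, 0.2 * exact$x - 9.01)
  expect_error(generate_synthetic_series(0.2, -9.01, 0:2, 0.01), "seed")
})

test_that("doping series from the printed endpoints recover the crossing", {
  # model through (0, +117) and (5, -80) Hz; noisy series refit
  slope <- (-80 - 117) / 5
  hits <- vapply(1:200, function(s) {
    d <- generate_synthetic_series(slope, 117, c(0, 1, 2, 3, 4, 5),
                                   noise_sd = 2, seed = s)
    as.numeric(doping_zero_crossing(d, x, y))
  }, numeric(1))
  expect_lt(max(abs(hits - 117 * 5 / 197)), 0.2)
})

test_that("the command-line interface runs over the installed package", {
  cli <- system.file("cli", "nmrcell.R", package = "nmrcell")
  expect_true(nzchar(cli))
  tab <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(label = c("interface", "bulk"), h_mm = c(0, 13),
                       peak_ppm = c(-0.195, 0)), tab, row.names = FALSE)
  out <- withr::local_tempfile(fileext = ".json")
  res <- system2("Rscript", c(cli, "extract-chi", "--table", shQuote(tab),
                              "--fraction-d2o", "0.99", "--out", shQuote(out)),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(attr(res, "status"), NULL)
  expect_true(file.exists(out))
  expect_equal(jsonlite::read_json(out)$chi_solid_reported, -9.4)
  # usage errors exit with status 2
  res2 <- suppressWarnings(
    system2("Rscript", c(cli, "extract-chi"), stdout = TRUE, stderr = TRUE))
  expect_equal(attr(res2, "status"), 2)
  res3 <- suppressWarnings(
    system2("Rscript", c(cli, "no-such-command"), stdout = TRUE,
            stderr = TRUE))
  expect_equal(attr(res3, "status"), 2)
})
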