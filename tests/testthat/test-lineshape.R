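# Spectra, widths, slice bandwidth and projections.

test_that("a uniform field gives a single Lorentzian at the uniform offset", {
  u <- make_uniform_field(-0.1)
  sp <- simulate_spectrum(u$field, u$chi_map, -9.01, linewidth_hz = 1)
  expect_equal(peak_position(sp), -0.1, tolerance = 1e-6)
  # half-maximum width equals the requested linewidth
  lw_ppm <- 1 / attr(sp, "spectrometer_mhz")
  above <- sp$ppm[sp$intensity >= max(sp$intensity) / 2]
  expect_equal(diff(range(above)), lw_ppm, tolerance = 0.3)
})

test_that("intensity is conserved through binning and convolution", {
  u <- make_uniform_field(0)
  # non-trivial field: linear gradient along z
  u$field$offset_ppm <- array(rep(seq(-0.05, 0.05,
                                      length.out = u$field$grid$counts[3]),
                                  each = 36),
                              u$field$grid$counts)
  coil <- coil_profile(center = 0, flat_length = 2, rolloff = 0.8)
  sp <- simulate_spectrum(u$field, u$chi_map, -9.01, coil = coil,
                          linewidth_hz = 2)
  w <- solvent_weight_map(u$chi_map, -9.01, coil = coil)
  expect_equal(sum(sp$intensity), sum(w$weight), tolerance = 1e-3)
  expect_equal(sum(attr(sp, "sticks")$weight), sum(w$weight),
               tolerance = 1e-12)
})

test_that("empty solvent selection is an explicit error", {
  u <- make_uniform_field(0)
  expect_error(simulate_spectrum(u$field, u$chi_map, solvent_chi = 0),
               "no solvent voxels")
  expect_error(simulate_spectrum(u$field, u$chi_map, -9.01,
                                 slice = slice_profile(99, 0.6)),
               "no contributing solvent voxels")
})

test_that("base width reads the stick support", {
  # two offset populations d apart: width = d
  u <- make_uniform_field(0, n = c(6, 6, 8))
  u$field$offset_ppm[, , 1:4] <- -0.02
  u$field$offset_ppm[, , 5:8] <- 0.01
  sp <- simulate_spectrum(u$field, u$chi_map, -9.01, linewidth_hz = 1)
  expect_equal(base_width(sp), 0.03, tolerance = 0.01)
  # a single stick has zero base width however broad the Lorentzian
  u2 <- make_uniform_field(-0.005)
  sp2 <- simulate_spectrum(u2$field, u2$chi_map, -9.01, linewidth_hz = 40)
  expect_equal(base_width(sp2), 0)
  expect_error(base_width(sp, threshold_fraction = 0.7))
})

test_that("peak ties break toward downfield", {
  u <- make_uniform_field(0, n = c(6, 6, 8))
  u$field$offset_ppm[, , 1:4] <- -0.02
  u$field$offset_ppm[, , 5:8] <- 0.02
  sp <- simulate_spectrum(u$field, u$chi_map, -9.01, linewidth_hz = 1)
  # bin-center quantization allows half a bin of slack; the point is that
  # the downfield member wins, not the upfield one at -0.02
  expect_equal(peak_position(sp), 0.02, tolerance = 0.01)
})

test_that("slice bandwidth follows gamma * G * dz", {
  # 11.5 G/cm and 0.6 mm: 42.577e6 Hz/T * 0.115 T/m * 6e-4 m
  expect_equal(slice_bandwidth(11.5, 0.6), 2937.813, tolerance = 1e-6)
  expect_equal(slice_bandwidth(11.5, 0), 0)
  expect_equal(slice_bandwidth(23, 0.6), 2 * slice_bandwidth(11.5, 0.6))
})

test_that("slice and coil profiles behave as documented", {
  co <- coil_profile(center = 0, flat_length = 10, rolloff = 2)
  expect_equal(coil_weight(co, c(-5, 0, 5)), c(1, 1, 1))
  expect_equal(coil_weight(co, c(-7.1, 7.1)), c(0, 0))
  expect_equal(coil_weight(co, 6), 0.5, tolerance = 1e-9)  # mid roll-off
  expect_equal(coil_weight(co, -6), coil_weight(co, 6))    # symmetry
  sl <- slice_profile(2, 0.6)
  z <- seq(0, 4, by = 0.01)
  expect_equal(sum(slice_weight(sl, z)) * 0.01, 0.6, tolerance = 0.02)
  slg <- slice_profile(2, 0.6, window = "gaussian")
  expect_equal(sum(slice_weight(slg, z)) * 0.01, 0.6, tolerance = 0.02)
})

test_that("projection profiles recover the expected shapes", {
  # uniform cube: rectangular z profile
  g <- voxel_grid(c(10, 10, 10), 0.5)
  cube <- structure(list(grid = g, chi = array(-9, g$counts),
                         background_chi = 0), class = "susceptibility_map")
  w <- solvent_weight_map(cube, -9)
  pz <- projection_profile(w, "z")
  expect_true(all(pz$weight == 100))
  # sphere: parabolic chord-area profile pi (R^2 - z^2)
  g2 <- voxel_grid(c(44, 44, 44), 0.1)
  m2 <- voxelize(scene(0) |> paint(shape_ellipsoid(c(2, 2, 2)), -9), g2,
                 supersampling = 1)
  w2 <- solvent_weight_map(m2, -9)
  p2 <- projection_profile(w2, "z")
  pred <- pi * pmax(2^2 - p2$mm^2, 0) / prod(g2$spacing[1:2])
  expect_gt(stats::cor(p2$weight, pred), 0.999)
  # microcell mask: z support equals the ellipsoid length
  g3 <- voxel_grid(c(32, 32, 100), 0.25)
  mc <- preset_scene("microcell", chi_solvent = -9.011, chi_solid = -9.4,
                     channel_diameter = 0)
  w3 <- solvent_weight_map(voxelize(mc, g3), -9.011)
  p3 <- projection_profile(w3, "z")
  support <- range(p3$mm[p3$weight > 0])
  # pure-solvent voxels stop a voxel or two short of the sharp tips
  expect_equal(diff(support), 2 * 11.5, tolerance = 0.05)
})

test_that("an interface slice holds about half the solvent of a bulk slice", {
  sc <- preset_scene("shigemi", chi_solvent = -9.011, chi_solid = -9.075,
                     solvent_height = 20, solid_length = 6)
  g <- voxel_grid(c(24, 24, 140), c(0.25, 0.25, 0.2), center = c(0, 0, 7))
  m <- voxelize(sc, g)
  w0 <- solvent_weight_map(m, -9.011, slice = slice_profile(0, 0.6))
  w13 <- solvent_weight_map(m, -9.011, slice = slice_profile(13, 0.6))
  expect_equal(sum(w0$weight) / sum(w13$weight), 0.5, tolerance = 0.1)
})

test_that("reversing the interface contrast mirrors the line shape", {
  g <- voxel_grid(c(24, 24, 140), c(0.25, 0.25, 0.2), center = c(0, 0, 7))
  mk <- function(chi_solid) {
    sc <- preset_scene("shigemi", chi_solvent = -9.011, chi_solid = chi_solid,
                       solvent_height = 18, solid_length = 5)
    sim <- simulate_field(sc, g, shimmed = TRUE, anisotropic = TRUE)
    simulate_spectrum(sim$field, sim$chi_map, -9.011,
                      coil = coil_profile(center = 5))
  }
  lo <- mk(-9.011 - 0.064)  # solid more diamagnetic: upfield shoulder
  hi <- mk(-9.011 + 0.064)  # reversed contrast: downfield shoulder
  st_lo <- attr(lo, "sticks"); st_hi <- attr(hi, "sticks")
  expect_lt(min(st_lo$ppm[st_lo$weight > 0]), -0.02)
  expect_gt(max(st_hi$ppm[st_hi$weight > 0]), 0.02)
  # antisymmetry: the mirrored stick supports coincide (up to binning)
  expect_equal(range(st_lo$ppm[st_lo$weight > 0]),
               -rev(range(st_hi$ppm[st_hi$weight > 0])),
               tolerance = 0.02)
})
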