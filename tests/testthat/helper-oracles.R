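# Independent oracles and small fixture builders used across tests.

# brute-force OLS via the normal equations (independent of stats::lm)
ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

# random susceptibility map (white noise, zero-centered) on a cubic grid
make_random_chi_map <- function(n = 32, spacing = 0.5, seed = 1,
                                amplitude = 0.5) {
  withr::with_seed(seed, {
    g <- voxel_grid(rep(n, 3), spacing)
    structure(list(grid = g,
                   chi = array(stats::runif(n^3, -amplitude, amplitude),
                               rep(n, 3)),
                   background_chi = 0),
              class = "susceptibility_map")
  })
}

# hand-built field/chi pair: uniform solvent with a prescribed offset field
make_uniform_field <- function(offsets, chi = -9.01, n = c(6, 6, 8),
                               spacing = 0.5) {
  g <- voxel_grid(n, spacing)
  chi_map <- structure(list(grid = g, chi = array(chi, n),
                            background_chi = chi_air()),
                       class = "susceptibility_map")
  field <- structure(list(grid = g, offset_ppm = array(offsets, n),
                          convention = "nuclear"),
                     class = "field_map")
  list(chi_map = chi_map, field = field)
}

solvent_97d2o <- function() {
  data.frame(fraction = c(0.97, 0.03), chi = c(chi_d2o(), chi_h2o()))
}

solvent_99d2o <- function() {
  data.frame(fraction = c(0.99, 0.01), chi = c(chi_d2o(), chi_h2o()))
}
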