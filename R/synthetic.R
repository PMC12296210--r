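# Synthetic calibration series: reproducible noisy measurements for
# fit-recovery studies.

#' Generate a synthetic linear calibration series
#'
#' Draws `y = intercept + slope * x + N(0, noise_sd)` at the given
#' design points under a fixed seed, for calibration-recovery tests of
#' the salt and doping models. Optionally writes an RFC-4180 CSV with a
#' provenance header (`#`-prefixed lines recording model, seed, noise).
#'
#' @param slope,intercept True model parameters.
#' @param xs Design points (e.g. NaCl molarities or doping mM).
#' @param noise_sd Gaussian noise standard deviation (same units as y).
#' @param seed Integer seed (required, recorded in the provenance).
#' @param path Optional CSV output path.
#' @return A tibble with columns `x` and `y` (and attribute
#'   `provenance`).
#' @examples
#' generate_synthetic_series(0.2, -9.01, c(0, 0.5, 1, 1.5, 2),
#'                           noise_sd = 0.01, seed = 7)
#' @export
generate_synthetic_series <- function(slope, intercept, xs, noise_sd, seed,
                                      path = NULL) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(is.numeric(xs), length(xs) >= 1, noise_sd >= 0)
  y <- withr::with_seed(as.integer(seed), {
    intercept + slope * xs + stats::rnorm(length(xs), sd = noise_sd)
  })
  out <- tibble::tibble(x = as.numeric(xs), y = y)
  prov <- c(
    sprintf("# synthetic linear series: y = %.10g + %.10g * x + N(0, %.10g)",
            intercept, slope, noise_sd),
    sprintf("# seed: %d", as.integer(seed)),
    sprintf("# generated by nmrcell %s",
            as.character(utils::packageVersion("nmrcell")))
  )
  attr(out, "provenance") <- prov
  if (!is.null(path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(prov, con)
    utils::write.csv(as.data.frame(out), con, row.names = FALSE)
  }
  out
}

#' Read a synthetic series CSV (skipping provenance lines)
#'
#' @param path CSV path written by [generate_synthetic_series()].
#' @return A tibble with `x`, `y` and the provenance lines as an
#'   attribute.
#' @export
read_synthetic_series <- function(path) {
  lines <- readLines(path)
  prov <- lines[startsWith(lines, "#")]
  df <- utils::read.csv(text = paste(lines[!startsWith(lines, "#")],
                                     collapse = "\n"))
  out <- tibble::as_tibble(df)
  attr(out, "provenance") <- prov
  out
}
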