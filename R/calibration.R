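# Linear calibrations: OLS fits for the salt-chi relation and the
# paramagnetic-doping shift series.

#' Ordinary least-squares linear calibration
#'
#' Fits `y = intercept + slope * x` by OLS (via [stats::lm()]). Used for
#' the NaCl-susceptibility relation and the cobalt(II)-doping shift
#' calibration.
#'
#' @param data Data frame holding the calibration points.
#' @param x,y Column names (tidy-eval) of predictor and response.
#' @return An object of class `linear_calibration`: list with `slope`,
#'   `intercept`, `residuals`, `n`, standard errors and the underlying
#'   `lm` fit. Has [generics::tidy()], [generics::glance()],
#'   [ggplot2::autoplot()] and `predict()` methods.
#' @examples
#' d <- data.frame(conc = c(0, 0.5, 1, 1.5, 2))
#' d$chi <- salt_chi(d$conc, "D2O")
#' fit_linear(d, conc, chi)
#' @export
fit_linear <- function(data, x, y) {
  stopifnot(is.data.frame(data))
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  ok <- is.finite(xv) & is.finite(yv)
  xv <- xv[ok]; yv <- yv[ok]
  if (length(xv) < 2) stop("a linear calibration needs at least 2 points")
  if (length(unique(xv)) < 2) stop("degenerate calibration: all x values identical")
  fit <- stats::lm(yv ~ xv)
  cf <- stats::coef(fit)
  # suppress the "essentially perfect fit" note for exact calibrations
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  structure(list(
    slope = unname(cf[2]), intercept = unname(cf[1]),
    se_slope = unname(se[2]), se_intercept = unname(se[1]),
    residuals = unname(stats::residuals(fit)),
    n = length(xv), x = xv, y = yv, fit = fit
  ), class = "linear_calibration")
}

#' @export
print.linear_calibration <- function(x, digits = 4, ...) {
  cat("<linear_calibration> n =", x$n, "\n")
  cat(sprintf("  slope     %.*g (se %.2g)\n", digits, x$slope, x$se_slope))
  cat(sprintf("  intercept %.*g (se %.2g)\n", digits, x$intercept, x$se_intercept))
  cat(sprintf("  residual sd %.3g\n", stats::sd(x$residuals)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a linear calibration
#'
#' @param x A `linear_calibration`.
#' @param ... Unused.
#' @return One row per model term with estimate, standard error,
#'   t statistic and p value.
#' @export
tidy.linear_calibration <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p.value = unname(s[, 4])
  )
}

#' @rdname tidy.linear_calibration
#' @export
glance.linear_calibration <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))
  tibble::tibble(
    r.squared = s$r.squared,
    sigma = s$sigma,
    nobs = x$n
  )
}

#' @export
predict.linear_calibration <- function(object, newdata, ...) {
  stopifnot(is.numeric(newdata))
  object$intercept + object$slope * newdata
}

#' Zero crossing of a doping calibration
#'
#' Fits a line to (concentration, shift) points and returns the
#' concentration at which the fitted interface shift crosses zero, i.e.
#' where the doped solid's susceptibility matches the solvent. When the
#' supplied shifts do not span a sign change, the crossing is an
#' extrapolation: it is still returned, with a warning and attribute
#' `extrapolated = TRUE`.
#'
#' @param data Data frame of calibration points.
#' @param conc,shift Column names (tidy-eval); concentration in mM,
#'   shift in Hz or ppm (units need only be consistent).
#' @return Matching concentration (mM) with attribute `extrapolated`.
#' @examples
#' doping_zero_crossing(data.frame(c = c(0, 5), s = c(117, -80)), c, s)
#' @export
doping_zero_crossing <- function(data, conc, shift) {
  cv <- rlang::eval_tidy(rlang::enquo(conc), data)
  sv <- rlang::eval_tidy(rlang::enquo(shift), data)
  cal <- fit_linear(data.frame(x = cv, y = sv), x, y)
  if (cal$slope == 0) stop("shift does not depend on concentration; no crossing")
  x0 <- -cal$intercept / cal$slope
  extrap <- !(min(sv) <= 0 && max(sv) >= 0)
  if (extrap) {
    warning("shifts do not span a sign change; zero crossing is extrapolated",
            call. = FALSE)
  }
  structure(x0, extrapolated = extrap)
}
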