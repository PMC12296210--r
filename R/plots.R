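# ggplot2 display methods.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated spectrum
#'
#' Intensity against offset, with the ppm axis reversed (downfield to
#' the left), the field's plotting convention.
#'
#' @param object An `nmr_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nmr_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ppm, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "offset (ppm)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.nmr_spectrum
#' @export
autoplot.linear_calibration <- function(object, ...) {
  df <- tibble::tibble(x = object$x, y = object$y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2) +
    ggplot2::labs(x = "x", y = "y") +
    ggplot2::theme_minimal()
}

#' On-axis field profile
#'
#' Nuclear offset along the z axis at the given xy position, as a
#' tibble or plot.
#'
#' @param field A `field_map`.
#' @param x,y Transverse position (mm).
#' @return A tibble with `z_mm` and `offset_ppm`.
#' @export
field_profile_z <- function(field, x = 0, y = 0) {
  stopifnot(inherits(field, "field_map"))
  pts <- cbind(x, y, field$grid$z)
  tibble::tibble(z_mm = field$grid$z, offset_ppm = field_at(field, pts))
}

#' @rdname field_profile_z
#' @export
plot_field_profile <- function(field, x = 0, y = 0) {
  df <- field_profile_z(field, x, y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z_mm, y = .data$offset_ppm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (mm)", y = "nuclear offset (ppm)") +
    ggplot2::theme_minimal()
}
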