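#' Regular voxel grid
#'
#' Defines a regular 3-D grid of voxel centers. The third axis is, by
#' convention, parallel to the static field B0; lengths are in mm and
#' voxel values are sampled at voxel centers.
#'
#' @param counts Integer vector of length 3: number of voxels per axis
#'   (each >= 4).
#' @param spacing Numeric vector of length 3 (or length 1, recycled):
#'   voxel spacing per axis in mm.
#' @param center Coordinates (mm) of the geometric center of the grid.
#'   Ignored when `origin` is given.
#' @param origin Coordinates (mm) of the center of voxel `[1, 1, 1]`.
#'   Overrides `center`.
#'
#' @return An object of class `voxel_grid`: a list with elements
#'   `counts`, `spacing`, `origin` and the per-axis coordinate vectors
#'   `x`, `y`, `z` (voxel-center coordinates in mm).
#' @examples
#' g <- voxel_grid(c(16, 16, 64), spacing = 0.5)
#' range(g$z)
#' @export
voxel_grid <- function(counts, spacing, center = c(0, 0, 0), origin = NULL) {
  counts <- as.integer(counts)
  stopifnot(length(counts) == 3, all(counts >= 4))
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(spacing) == 3, all(spacing > 0))
  if (is.null(origin)) {
    stopifnot(length(center) == 3)
    origin <- center - (counts - 1) / 2 * spacing
  }
  stopifnot(length(origin) == 3, all(is.finite(origin)))
  g <- list(
    counts = counts, spacing = as.numeric(spacing), origin = as.numeric(origin),
    x = origin[1] + (seq_len(counts[1]) - 1) * spacing[1],
    y = origin[2] + (seq_len(counts[2]) - 1) * spacing[2],
    z = origin[3] + (seq_len(counts[3]) - 1) * spacing[3]
  )
  class(g) <- "voxel_grid"
  g
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("<voxel_grid> ", paste(x$counts, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm\n  extent x [", signif(min(x$x), 4), ", ", signif(max(x$x), 4),
      "] y [", signif(min(x$y), 4), ", ", signif(max(x$y), 4),
      "] z [", signif(min(x$z), 4), ", ", signif(max(x$z), 4), "] mm\n", sep = "")
  invisible(x)
}

#' Voxel-center coordinates of a grid
#'
#' @param grid A [voxel_grid()].
#' @return A `prod(counts)` x 3 matrix of voxel-center coordinates (mm),
#'   in array (column-major) order: the first axis varies fastest.
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  n <- grid$counts
  cbind(
    rep(grid$x, times = n[2] * n[3]),
    rep(rep(grid$y, each = n[1]), times = n[3]),
    rep(grid$z, each = n[1] * n[2])
  )
}

#' Voxel volume of a grid in microliters
#'
#' One cubic millimeter equals one microliter, so the voxel volume in
#' mm^3 is reported directly as uL.
#'
#' @param grid A [voxel_grid()].
#' @return Voxel volume in uL (= mm^3).
#' @export
voxel_volume_ul <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  prod(grid$spacing)
}

grid_equal <- function(a, b, tol = 1e-9) {
  all(a$counts == b$counts) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}
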