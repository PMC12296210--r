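#' Geometric primitives for scene construction
#'
#' Shapes are simple constructive-solid-geometry (CSG) primitives used to
#' paint susceptibility values onto a background. All lengths are in mm;
#' the z axis is parallel to B0. Supported variants: half-space, finite
#' z-aligned cylinder, ellipsoid, union and difference composites.
#'
#' @param z0 Plane height (mm) for the half-space boundary.
#' @param side `"below"` (z < z0) or `"above"` (z > z0).
#' @return An object of class `nmr_shape`.
#' @examples
#' glass <- shape_halfspace(0, "below")
#' shape_contains(glass, cbind(0, 0, c(-1, 1)))
#' @export
shape_halfspace <- function(z0 = 0, side = c("below", "above")) {
  side <- match.arg(side)
  stopifnot(is.finite(z0))
  structure(list(type = "halfspace", z0 = z0, side = side), class = "nmr_shape")
}

#' @rdname shape_halfspace
#' @param radius Cylinder radius (mm), > 0. The cylinder axis is parallel
#'   to z (the B0 axis).
#' @param zmin,zmax Axial extent (mm), `zmin < zmax`.
#' @param center_xy Axis position in the xy plane (mm).
#' @export
shape_cylinder <- function(radius, zmin, zmax, center_xy = c(0, 0)) {
  stopifnot(radius > 0, zmin < zmax, length(center_xy) == 2)
  structure(list(type = "cylinder", radius = radius, zmin = zmin, zmax = zmax,
                 center_xy = as.numeric(center_xy)), class = "nmr_shape")
}

#' @rdname shape_halfspace
#' @param semi_axes Ellipsoid semi-axes `c(a, b, c)` in mm, all > 0; the
#'   third semi-axis is along z (B0).
#' @param center Ellipsoid center (mm).
#' @export
shape_ellipsoid <- function(semi_axes, center = c(0, 0, 0)) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0), length(center) == 3)
  structure(list(type = "ellipsoid", semi_axes = as.numeric(semi_axes),
                 center = as.numeric(center)), class = "nmr_shape")
}

#' @rdname shape_halfspace
#' @param ... Child shapes (at least one) for the union.
#' @param disjoint Logical; caller's assertion that the children are
#'   pairwise disjoint, which makes the union's analytic volume the sum
#'   of the children's volumes.
#' @export
shape_union <- function(..., disjoint = TRUE) {
  children <- list(...)
  stopifnot(length(children) >= 1, all(vapply(children, inherits, TRUE, "nmr_shape")))
  structure(list(type = "union", children = children, disjoint = isTRUE(disjoint)),
            class = "nmr_shape")
}

#' @rdname shape_halfspace
#' @param a,b Shapes; the difference contains points in `a` but not `b`.
#' @export
shape_difference <- function(a, b) {
  stopifnot(inherits(a, "nmr_shape"), inherits(b, "nmr_shape"))
  structure(list(type = "difference", children = list(a, b)), class = "nmr_shape")
}

#' Point-in-shape test
#'
#' Deterministic containment test for any set of points. Boundary points
#' (distance exactly on the surface) are counted as contained.
#'
#' @param shape An `nmr_shape`.
#' @param points An n x 3 matrix of coordinates (mm).
#' @return Logical vector of length n.
#' @export
shape_contains <- function(shape, points) {
  stopifnot(inherits(shape, "nmr_shape"))
  points <- matrix(as.numeric(points), ncol = 3)
  switch(shape$type,
    halfspace = if (shape$side == "below") points[, 3] <= shape$z0 else points[, 3] >= shape$z0,
    cylinder = {
      dx <- points[, 1] - shape$center_xy[1]
      dy <- points[, 2] - shape$center_xy[2]
      (dx * dx + dy * dy <= shape$radius^2) &
        points[, 3] >= shape$zmin & points[, 3] <= shape$zmax
    },
    ellipsoid = {
      u <- (points[, 1] - shape$center[1]) / shape$semi_axes[1]
      v <- (points[, 2] - shape$center[2]) / shape$semi_axes[2]
      w <- (points[, 3] - shape$center[3]) / shape$semi_axes[3]
      u * u + v * v + w * w <= 1
    },
    union = {
      inside <- rep(FALSE, nrow(points))
      for (ch in shape$children) inside <- inside | shape_contains(ch, points)
      inside
    },
    difference = shape_contains(shape$children[[1]], points) &
      !shape_contains(shape$children[[2]], points),
    stop("unknown shape type: ", shape$type)
  )
}

#' Closed-form volume of a shape
#'
#' Exact analytic volume for primitives and for unions of pairwise
#' disjoint children. Composites without a closed form (differences,
#' overlapping unions) raise an unsupported-geometry error; callers may
#' fall back to voxel counting via [voxelize()].
#'
#' @param shape An `nmr_shape`.
#' @return Volume in uL (= mm^3).
#' @examples
#' # measured access-channel dimensions: d = 1.3 mm, L = 8.5 mm
#' analytic_volume(shape_cylinder(1.3 / 2, 0, 8.5))
#' @export
analytic_volume <- function(shape) {
  stopifnot(inherits(shape, "nmr_shape"))
  switch(shape$type,
    cylinder = pi * shape$radius^2 * (shape$zmax - shape$zmin),
    ellipsoid = 4 / 3 * pi * prod(shape$semi_axes),
    halfspace = stop("unsupported geometry: a half-space has infinite volume"),
    union = {
      if (!isTRUE(shape$disjoint)) {
        stop("unsupported geometry: union not declared disjoint has no closed-form volume")
      }
      sum(vapply(shape$children, analytic_volume, numeric(1)))
    },
    stop("unsupported geometry: no closed-form volume for type '", shape$type, "'")
  )
}

# Smallest finite feature size (mm) along each axis, NA when unbounded.
# Used for the feature-under-resolution warning in voxelize().
shape_feature_sizes <- function(shape) {
  switch(shape$type,
    halfspace = c(NA_real_, NA_real_, NA_real_),
    cylinder = c(2 * shape$radius, 2 * shape$radius, shape$zmax - shape$zmin),
    ellipsoid = 2 * shape$semi_axes,
    union = ,
    difference = {
      m <- do.call(rbind, lapply(shape$children, shape_feature_sizes))
      suppressWarnings(apply(m, 2, min, na.rm = TRUE))
    }
  )
}
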