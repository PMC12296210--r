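# Printable microcell design: dimensions, analytic volumes, and a
# watertight triangle mesh of the resin solid.

#' Ellipsoidal microcell design
#'
#' Parametric design of the printed cell: an ellipsoidal cavity (long
#' axis along B0/z) inside a wall of constant thickness, with an
#' optional cylindrical access channel through the top wall, extended as
#' a neck. Defaults follow the printed cell: interior semi-axes
#' 1.65 x 1.65 x 11.5 mm, measured channel bore 1.3 mm diameter x
#' 8.5 mm, wall 0.3 mm.
#'
#' @param semi_axes Interior semi-axes `c(a, b, c)` in mm, `c` along z.
#' @param wall Wall thickness (mm), > 0.
#' @param channel_diameter Access-channel bore diameter (mm); 0 or
#'   `NULL` disables the channel.
#' @param channel_length Channel bore length (mm), measured from the
#'   interior ellipsoid surface.
#' @return Object of class `cell_design` with derived analytic volumes
#'   (uL): `ellipsoid_volume_ul`, `channel_volume_ul`,
#'   `total_volume_ul` (ellipsoid + channel - their overlap).
#' @examples
#' d <- cell_design()
#' d$total_volume_ul
#' @export
cell_design <- function(semi_axes = c(1.65, 1.65, 11.5), wall = 0.3,
                        channel_diameter = 1.3, channel_length = 8.5) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0))
  if (!(wall > 0)) stop("wall thickness must be > 0")
  if (is.null(channel_diameter)) channel_diameter <- 0
  stopifnot(channel_diameter >= 0)
  has_channel <- channel_diameter > 0
  if (has_channel) {
    stopifnot(channel_length > 0)
    if (channel_diameter / 2 >= semi_axes[1]) {
      stop("channel wider than the cell interior")
    }
    if (abs(semi_axes[1] - semi_axes[2]) > 1e-12 * semi_axes[1]) {
      stop("the access channel requires an axisymmetric cell (a == b)")
    }
  }
  a <- semi_axes[1]; b <- semi_axes[2]; cc <- semi_axes[3]
  v_ell <- 4 / 3 * pi * a * b * cc
  if (has_channel) {
    r <- channel_diameter / 2
    z_in <- cc * sqrt(1 - (r / a)^2)  # bore meets the interior surface
    v_chan <- pi * r^2 * channel_length
    # overlap: ellipsoid cap above z_in (entirely within the bore radius)
    v_cap <- pi * a * b * (2 * cc / 3 - z_in + z_in^3 / (3 * cc^2))
    v_total <- v_ell + v_chan - v_cap
  } else {
    v_chan <- 0
    v_total <- v_ell
  }
  structure(list(
    semi_axes = as.numeric(semi_axes), wall = wall,
    channel_diameter = channel_diameter,
    channel_length = if (has_channel) channel_length else 0,
    ellipsoid_volume_ul = v_ell,
    channel_volume_ul = v_chan,
    total_volume_ul = v_total
  ), class = "cell_design")
}

#' @export
print.cell_design <- function(x, ...) {
  cat("<cell_design> interior", paste(x$semi_axes, collapse = " x "),
      "mm (semi-axes), wall", x$wall, "mm\n")
  if (x$channel_diameter > 0) {
    cat("  access channel d =", x$channel_diameter, "mm, L =",
        x$channel_length, "mm\n")
  }
  cat(sprintf("  volumes: ellipsoid %.1f uL, channel %.2f uL, total %.1f uL\n",
              x$ellipsoid_volume_ul, x$channel_volume_ul, x$total_volume_ul))
  invisible(x)
}

#' Analytic volume of the printed resin solid
#'
#' Volume of the wall material itself (outer minus inner ellipsoid,
#' corrected for the channel opening and neck). Used to check mesh
#' volume convergence.
#'
#' @param design A [cell_design()].
#' @return Solid volume in uL.
#' @export
design_solid_volume <- function(design) {
  stopifnot(inherits(design, "cell_design"))
  ai <- design$semi_axes
  ao <- ai + design$wall
  vol_ell <- function(s) 4 / 3 * pi * prod(s)
  cap <- function(s, z0) pi * s[1] * s[2] * (2 * s[3] / 3 - z0 + z0^3 / (3 * s[3]^2))
  if (design$channel_diameter == 0) return(vol_ell(ao) - vol_ell(ai))
  r <- design$channel_diameter / 2
  rn <- r + design$wall
  z_i <- ai[3] * sqrt(1 - (r / ai[1])^2)
  z_o <- ao[3] * sqrt(1 - (rn / ao[1])^2)
  z_top <- z_i + design$channel_length
  outer_solid <- vol_ell(ao) - cap(ao, z_o) + pi * rn^2 * (z_top - z_o)
  inner_void <- vol_ell(ai) - cap(ai, z_i) + pi * r^2 * (z_top - z_i)
  outer_solid - inner_void
}

# --- mesh construction -----------------------------------------------

new_mesh <- function(vertices, faces) {
  structure(list(vertices = vertices, faces = faces), class = "cell_mesh")
}

# ring of n points at angle positions phi, given xy radii and height
mesh_ring <- function(rx, ry, z, n) {
  phi <- 2 * pi * (seq_len(n) - 1) / n
  cbind(rx * cos(phi), ry * sin(phi), z)
}

# triangles stitching ring i1 (length n) to ring i2; `flip` reverses
# orientation
stitch_rings <- function(i1, i2, flip = FALSE) {
  n <- length(i1)
  k <- seq_len(n)
  k2 <- c(2:n, 1L)
  tris <- rbind(cbind(i1[k], i2[k], i2[k2]),
                cbind(i1[k], i2[k2], i1[k2]))
  if (flip) tris[, c(1, 3, 2)] else tris
}

fan_to_pole <- function(ring, pole, flip = FALSE) {
  n <- length(ring)
  k <- seq_len(n)
  k2 <- c(2:n, 1L)
  tris <- cbind(ring[k], ring[k2], rep(pole, n))
  if (flip) tris[, c(1, 3, 2)] else tris
}

#' Triangle mesh of the microcell solid
#'
#' Builds a watertight mesh of the printed solid: the ellipsoidal shell
#' (outer surface outward-oriented, cavity surface inward) and, when the
#' channel is enabled, the neck tube and its top rim annulus. The
#' ellipsoid surfaces are meshed as polar zones whose opening rings
#' coincide exactly with the neck cylinder rings, which guarantees a
#' closed 2-manifold.
#'
#' @param design A [cell_design()].
#' @param facet_count Target number of triangular facets (>= 64); the
#'   mesh volume converges to [design_solid_volume()] as this grows.
#' @return A `cell_mesh`: list with `vertices` (n x 3, mm) and `faces`
#'   (m x 3 vertex indices, outward-wound).
#' @export
design_mesh <- function(design, facet_count = 5000) {
  stopifnot(inherits(design, "cell_design"))
  if (facet_count < 64) stop("facet_count must be >= 64")
  ai <- design$semi_axes
  ao <- ai + design$wall
  nph <- max(8L, as.integer(floor(sqrt(facet_count / 4))))
  nth <- nph

  verts <- matrix(numeric(0), ncol = 3)
  faces <- matrix(integer(0), ncol = 3)
  add_ring <- function(rx, ry, z) {
    i0 <- nrow(verts)
    verts <<- rbind(verts, mesh_ring(rx, ry, z, nph))
    i0 + seq_len(nph)
  }
  add_pole <- function(x, y, z) {
    verts <<- rbind(verts, c(x, y, z))
    nrow(verts)
  }
  add_faces <- function(f) faces <<- rbind(faces, f)

  # ellipsoid zone from theta0 (opening) down to the south pole;
  # returns the opening ring indices. outward = TRUE for the outer
  # surface of the solid.
  zone <- function(axes, theta0, outward) {
    thetas <- seq(theta0, pi, length.out = nth + 1L)
    rings <- lapply(thetas[-length(thetas)], function(th) {
      add_ring(axes[1] * sin(th), axes[2] * sin(th), axes[3] * cos(th))
    })
    pole <- add_pole(0, 0, -axes[3])
    for (j in seq_len(length(rings) - 1L)) {
      add_faces(stitch_rings(rings[[j]], rings[[j + 1L]], flip = !outward))
    }
    # south cap: unflipped fan winds inward, so flip for the outer surface
    add_faces(fan_to_pole(rings[[length(rings)]], pole, flip = outward))
    rings[[1L]]
  }

  if (design$channel_diameter == 0) {
    # closed shell: full outer ellipsoid + full inner ellipsoid (inverted)
    closed_ellipsoid <- function(axes, outward) {
      thetas <- seq(0, pi, length.out = nth + 1L)[-c(1, nth + 1L)]
      rings <- lapply(thetas, function(th) {
        add_ring(axes[1] * sin(th), axes[2] * sin(th), axes[3] * cos(th))
      })
      np <- add_pole(0, 0, axes[3])
      sp <- add_pole(0, 0, -axes[3])
      add_faces(fan_to_pole(rings[[1L]], np, flip = !outward))
      for (j in seq_len(length(rings) - 1L)) {
        add_faces(stitch_rings(rings[[j]], rings[[j + 1L]], flip = !outward))
      }
      add_faces(fan_to_pole(rings[[length(rings)]], sp, flip = outward))
    }
    closed_ellipsoid(ao, TRUE)
    closed_ellipsoid(ai, FALSE)
    return(new_mesh(verts, faces))
  }

  r <- design$channel_diameter / 2
  rn <- r + design$wall
  if (rn >= ao[1]) stop("channel neck wider than the cell exterior")
  th_o <- asin(rn / ao[1])
  th_i <- asin(r / ai[1])
  z_i <- ai[3] * cos(th_i)
  z_top <- z_i + design$channel_length
  z_o <- ao[3] * cos(th_o)

  ring_out_open <- zone(ao, th_o, outward = TRUE)   # at radius rn, z_o
  ring_in_open <- zone(ai, th_i, outward = FALSE)   # at radius r, z_i
  ring_out_top <- add_ring(rn, rn, z_top)
  ring_in_top <- add_ring(r, r, z_top)
  # neck outer wall (outward), from top down to the outer-ellipsoid opening
  add_faces(stitch_rings(ring_out_top, ring_out_open, flip = FALSE))
  # neck bore wall (inward), from top down to the inner-ellipsoid opening
  add_faces(stitch_rings(ring_in_top, ring_in_open, flip = TRUE))
  # top rim annulus, normal +z
  add_faces(stitch_rings(ring_in_top, ring_out_top, flip = FALSE))
  new_mesh(verts, faces)
}

#' Mesh volume and watertightness
#'
#' `mesh_volume()` computes the signed volume by the divergence theorem
#' (sum of signed tetrahedra); it is positive for an outward-wound
#' closed mesh. `mesh_is_watertight()` checks that every undirected edge
#' is shared by exactly two faces with opposite directions (closed,
#' consistently oriented 2-manifold).
#'
#' @param mesh A `cell_mesh` (or any list with `vertices` and `faces`).
#' @return Volume in uL; or a logical.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  s <- a[, 1] * (b[, 2] * c3[, 3] - b[, 3] * c3[, 2]) -
    a[, 2] * (b[, 1] * c3[, 3] - b[, 3] * c3[, 1]) +
    a[, 3] * (b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  sum(s) / 6
}

#' @rdname mesh_volume
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  ed <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  fwd <- paste(ed[, 1], ed[, 2])
  rev_ <- paste(ed[, 2], ed[, 1])
  # no duplicated directed edge, and every edge's reverse present
  !anyDuplicated(fwd) && all(fwd %in% rev_)
}
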