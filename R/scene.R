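#' Susceptibility scenes
#'
#' A scene is an ordered list of (shape, chi) layers painted last-wins
#' over a uniform background susceptibility. The background defaults to
#' air (+0.36 ppm); interface measurements depend only on same-medium
#' frequency differences and are insensitive to this choice.
#'
#' @param background_chi Background volume susceptibility in ppm.
#' @return An object of class `nmr_scene`.
#' @examples
#' sc <- scene() |>
#'   paint(shape_cylinder(2.1, 0, 40), chi_d2o())
#' scene_chi(sc, cbind(0, 0, c(-1, 1)))
#' @export
scene <- function(background_chi = chi_air()) {
  stopifnot(is.finite(background_chi))
  structure(list(background_chi = background_chi, layers = list()),
            class = "nmr_scene")
}

#' @rdname scene
#' @param x An `nmr_scene`.
#' @param shape An [shape_halfspace()] family shape.
#' @param chi Volume susceptibility (ppm) painted inside `shape`.
#' @param label Optional material label carried through for reporting.
#' @export
paint <- function(x, shape, chi, label = NULL) {
  stopifnot(inherits(x, "nmr_scene"), inherits(shape, "nmr_shape"), is.finite(chi))
  x$layers[[length(x$layers) + 1]] <- list(shape = shape, chi = as.numeric(chi),
                                           label = label)
  x
}

#' Evaluate a scene's susceptibility at points
#'
#' Layers are applied in painting order (last wins).
#'
#' @param scene An `nmr_scene`.
#' @param points n x 3 matrix of coordinates (mm).
#' @return Numeric vector of chi values (ppm).
#' @export
scene_chi <- function(scene, points) {
  stopifnot(inherits(scene, "nmr_scene"))
  points <- matrix(as.numeric(points), ncol = 3)
  chi <- rep(scene$background_chi, nrow(points))
  for (layer in scene$layers) {
    inside <- shape_contains(layer$shape, points)
    chi[inside] <- layer$chi
  }
  chi
}

#' @export
print.nmr_scene <- function(x, ...) {
  cat("<nmr_scene> background chi =", x$background_chi, "ppm,",
      length(x$layers), "painted layer(s)\n")
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  [%d] %s chi = %g ppm%s\n", i, l$shape$type, l$chi,
                if (is.null(l$label)) "" else paste0(" (", l$label, ")")))
  }
  invisible(x)
}

#' Preset sample-cell scenes
#'
#' Builds the three measurement geometries used throughout the package:
#'
#' * `"shigemi"`: a solvent column (tube inner diameter 4.2 mm) above a
#'   susceptibility-matched glass column, flat interface at z = 0.
#' * `"plug_in_tube"`: a printed resin plug (4.0 mm OD, 20 mm long)
#'   below a solvent column inside a 4.2 mm ID tube; the thin solvent
#'   annulus between plug and tube wall is included.
#' * `"microcell"`: a solvent-filled ellipsoidal cavity inside a printed
#'   resin shell (long axis along B0), with an optional cylindrical
#'   access channel through the top wall, inside an otherwise solvent-
#'   free tube.
#'
#' Interface presets (`"shigemi"`, `"plug_in_tube"`) also carry a
#' matched-reference scene (the solid replaced by solvent) as attribute
#' `"shim_reference"`. Subtracting the reference field emulates shimming
#' the magnet on a matched, solid-free sample, which removes tube-end
#' gradients common to both samples.
#'
#' @param name Preset name.
#' @param chi_solvent,chi_solid Volume susceptibilities (ppm) of solvent
#'   and solid (glass or resin). Both required.
#' @param background_chi Background susceptibility (ppm), default air.
#' @param tube_id Tube inner diameter (mm).
#' @param solvent_height Height of the solvent column above the
#'   interface (mm) for the interface presets.
#' @param solid_length Length of the glass/resin column below the
#'   interface (mm).
#' @param semi_axes Microcell interior semi-axes (mm).
#' @param wall Microcell wall thickness (mm).
#' @param channel_diameter,channel_length Access-channel bore diameter
#'   and length (mm); set `channel_diameter = 0` (or `NULL`) to disable
#'   the channel.
#' @return An `nmr_scene`; interface presets carry a `"shim_reference"`
#'   attribute.
#' @examples
#' sc <- preset_scene("shigemi", chi_solvent = -9.011, chi_solid = -9.075)
#' length(sc$layers)
#' @export
preset_scene <- function(name = c("shigemi", "plug_in_tube", "microcell"),
                         chi_solvent, chi_solid,
                         background_chi = chi_air(),
                         tube_id = 4.2,
                         solvent_height = 42,
                         solid_length = if (name == "plug_in_tube") 20 else 8,
                         semi_axes = c(1.65, 1.65, 11.5),
                         wall = 0.3,
                         channel_diameter = 1.3,
                         channel_length = 8.5) {
  name <- match.arg(name)
  if (missing(chi_solvent) || missing(chi_solid)) {
    stop("preset_scene() needs chi values for both materials (chi_solvent, chi_solid)")
  }
  r_tube <- tube_id / 2
  if (name == "shigemi") {
    sc <- scene(background_chi) |>
      paint(shape_cylinder(r_tube, -solid_length, 0), chi_solid, "glass") |>
      paint(shape_cylinder(r_tube, 0, solvent_height), chi_solvent, "solvent")
    ref <- scene(background_chi) |>
      paint(shape_cylinder(r_tube, -solid_length, solvent_height), chi_solvent, "solvent")
    attr(sc, "shim_reference") <- ref
    return(sc)
  }
  if (name == "plug_in_tube") {
    # solvent fills the tube bore; the plug (OD 4.0 mm) overpaints its core
    sc <- scene(background_chi) |>
      paint(shape_cylinder(r_tube, -solid_length, solvent_height), chi_solvent, "solvent") |>
      paint(shape_cylinder(2.0, -solid_length, 0), chi_solid, "resin plug")
    ref <- scene(background_chi) |>
      paint(shape_cylinder(r_tube, -solid_length, solvent_height), chi_solvent, "solvent")
    attr(sc, "shim_reference") <- ref
    return(sc)
  }
  # microcell: interior ellipsoid centered at origin, long (third) axis along z
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0), wall > 0)
  outer_axes <- semi_axes + wall
  sc <- scene(background_chi) |>
    paint(shape_ellipsoid(outer_axes), chi_solid, "resin shell")
  has_channel <- !is.null(channel_diameter) && channel_diameter > 0
  if (has_channel) {
    r_ch <- channel_diameter / 2
    if (r_ch >= semi_axes[1]) stop("channel wider than the cell interior")
    # bore starts where the channel meets the interior ellipsoid surface
    z_in <- semi_axes[3] * sqrt(1 - (r_ch / semi_axes[1])^2)
    sc <- sc |>
      paint(shape_cylinder(r_ch + wall, z_in, z_in + channel_length),
            chi_solid, "channel neck")
  }
  sc <- sc |> paint(shape_ellipsoid(semi_axes), chi_solvent, "solvent cavity")
  if (has_channel) {
    sc <- sc |>
      paint(shape_cylinder(channel_diameter / 2, z_in, z_in + channel_length),
            chi_solvent, "channel bore")
  }
  sc
}
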