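# Vessel geometry and physical property records.
#
# Coordinate convention: origin at the inner bottom corner of the liquid
# cavity; x spans the width, y the depth/thickness (light propagates along
# +y), z the height. The glass walls sit at y in [-glass_thickness, 0) and
# (thickness, thickness + glass_thickness]; `thickness` is the inner liquid
# depth, so liquid volume is width * thickness * fill_height.

#' Flat-panel reactor geometry
#'
#' Builds a validated geometry record for the customized 380 ml flat-panel
#' vessel. Defaults are the vessel, sparger and anchor-stirrer dimensions of
#' the physical reactor; `fill_height` defaults to the value giving a 380 ml
#' working volume. Probe/sparger/anchor placements are configurable because
#' only their sizes, not their exact positions, are fixed by the hardware.
#'
#' @param height Inner vessel height (m).
#' @param width Inner vessel width (m).
#' @param thickness Inner liquid depth along the light path (m).
#' @param glass_thickness Thickness of each glass face (m); must be smaller
#'   than `thickness`.
#' @param sparger_inlet_diameter,sparger_hole_diameter,sparger_hole_count,sparger_length
#'   Gas sparger dimensions (m, m, count, m).
#' @param anchor_diameter,anchor_length Anchor stirring-bar dimensions (m).
#' @param fill_height Liquid fill height (m), at most `height`.
#' @param probe_diameter Diameter of the O2/pH probes (m).
#' @param probe_depth How far the probes descend from the lid (m).
#' @param probe_x x positions of the probe axes (m); vector, one per probe.
#' @param probe_y y position (depth) of the probe axes (m).
#' @return An object of class `pbr_geometry` (named list of dimensions).
#' @examples
#' geom <- reactor_geometry()
#' liquid_volume(geom) # ~3.8e-4 m^3 = 380 ml
#' @export
reactor_geometry <- function(height = 0.1983,
                             width = 0.11,
                             thickness = 0.024,
                             glass_thickness = 0.0033,
                             sparger_inlet_diameter = 0.002,
                             sparger_hole_diameter = 0.0004,
                             sparger_hole_count = 7L,
                             sparger_length = 0.03,
                             anchor_diameter = 0.006,
                             anchor_length = 0.035,
                             fill_height = 0.1439,
                             probe_diameter = 0.012,
                             probe_depth = 0.12,
                             probe_x = c(0.030, 0.080),
                             probe_y = 0.016) {
  geom <- list(
    height = height, width = width, thickness = thickness,
    glass_thickness = glass_thickness,
    sparger_inlet_diameter = sparger_inlet_diameter,
    sparger_hole_diameter = sparger_hole_diameter,
    sparger_hole_count = as.integer(sparger_hole_count),
    sparger_length = sparger_length,
    anchor_diameter = anchor_diameter, anchor_length = anchor_length,
    fill_height = fill_height,
    probe_diameter = probe_diameter, probe_depth = probe_depth,
    probe_x = probe_x, probe_y = probe_y
  )
  lengths <- geom[c("height", "width", "thickness", "glass_thickness",
                    "sparger_inlet_diameter", "sparger_hole_diameter",
                    "sparger_length", "anchor_diameter", "anchor_length")]
  if (any(!vapply(lengths, is.numeric, logical(1))) ||
      any(unlist(lengths) <= 0)) {
    abort("All geometry lengths must be positive numbers.")
  }
  if (fill_height < 0 || fill_height > height) {
    abort("`fill_height` must lie in [0, height].")
  }
  if (glass_thickness >= thickness) {
    abort("`glass_thickness` must be smaller than `thickness`.")
  }
  if (geom$sparger_hole_count < 1L) abort("`sparger_hole_count` must be >= 1.")
  structure(geom, class = "pbr_geometry")
}

#' @export
print.pbr_geometry <- function(x, ...) {
  cat("<pbr_geometry> flat-panel vessel\n")
  cat(sprintf("  cavity: %.4f x %.4f x %.4f m (W x D x H), glass %.4f m\n",
              x$width, x$thickness, x$height, x$glass_thickness))
  cat(sprintf("  fill height %.4f m -> working volume %.1f ml\n",
              x$fill_height, 1e6 * liquid_volume(x)))
  invisible(x)
}

#' Fluid (culture medium) properties
#'
#' @param dynamic_viscosity Dynamic viscosity eta (Pa s).
#' @param fluid_density Fluid density rho (kg m^-3).
#' @param gravity Gravitational acceleration (m s^-2).
#' @return An object of class `pbr_fluid`.
#' @export
fluid_properties <- function(dynamic_viscosity = 1e-3,
                             fluid_density = 1000,
                             gravity = 9.81) {
  if (dynamic_viscosity < 0) abort("`dynamic_viscosity` must be >= 0.")
  if (fluid_density <= 0) abort("`fluid_density` must be > 0.")
  if (gravity < 0) abort("`gravity` must be >= 0.")
  structure(list(dynamic_viscosity = dynamic_viscosity,
                 fluid_density = fluid_density, gravity = gravity),
            class = "pbr_fluid")
}

#' Cell (particle) properties
#'
#' Cells are modelled as spherical particles of fixed density; `cell_absorptance`
#' is the fraction of the locally perceived irradiance a cell absorbs.
#'
#' @param particle_density Cell density rho_p (kg m^-3).
#' @param particle_diameter Cell diameter d_p (m).
#' @param initial_particle_mass Initial cell mass m_p (kg).
#' @param cell_absorptance Dimensionless absorptance in `[0, 1]`.
#' @return An object of class `pbr_cell`.
#' @export
cell_properties <- function(particle_density = 1050,
                            particle_diameter = 2e-6,
                            initial_particle_mass = 4.4e-15,
                            cell_absorptance = 0.55) {
  if (particle_density <= 0 || particle_diameter <= 0 ||
      initial_particle_mass <= 0) {
    abort("Particle density, diameter and mass must all be > 0.")
  }
  if (cell_absorptance < 0 || cell_absorptance > 1) {
    abort("`cell_absorptance` must lie in [0, 1].")
  }
  structure(list(particle_density = particle_density,
                 particle_diameter = particle_diameter,
                 initial_particle_mass = initial_particle_mass,
                 cell_absorptance = cell_absorptance),
            class = "pbr_cell")
}

#' Working liquid volume
#'
#' @param geom A [reactor_geometry()].
#' @param fill_height Optional override of the geometry's fill height (m).
#' @return Liquid volume in m^3 (linear in fill height).
#' @export
liquid_volume <- function(geom, fill_height = geom$fill_height) {
  stopifnot(inherits(geom, "pbr_geometry"))
  if (any(fill_height < 0)) abort("`fill_height` must be >= 0.")
  geom$width * geom$thickness * fill_height
}

#' Classify points into vessel domains
#'
#' Maps 3-D positions to the domain they fall in. The labels partition the
#' bounding box `[0, width] x [-glass_thickness, thickness + glass_thickness]
#' x [0, height]`; anything outside is `exterior`. Internal fittings take
#' precedence over the liquid: probes, then sparger, then the cylindrical
#' zone swept by the rotating anchor stirrer.
#'
#' @param geom A [reactor_geometry()].
#' @param points A data frame / tibble with columns `x`, `y`, `z` (m), or a
#'   numeric length-3 vector.
#' @param include_internals If `FALSE`, probes/sparger/stirrer are ignored
#'   and their space is labelled liquid or headspace.
#' @return A character vector of labels, one per point, from
#'   `{glass, liquid, headspace, probe, sparger, stirrer_zone, exterior}`.
#' @export
domain_at <- function(geom, points, include_internals = TRUE) {
  stopifnot(inherits(geom, "pbr_geometry"))
  if (is.numeric(points) && is.null(dim(points))) {
    points <- tibble::tibble(x = points[1], y = points[2], z = points[3])
  }
  x <- points$x; y <- points$y; z <- points$z
  tg <- geom$glass_thickness
  inside_xz <- x >= 0 & x <= geom$width & z >= 0 & z <= geom$height
  lab <- rep("exterior", length(x))
  in_glass <- inside_xz & ((y >= -tg & y < 0) |
                           (y > geom$thickness & y <= geom$thickness + tg))
  in_cavity <- inside_xz & y >= 0 & y <= geom$thickness
  lab[in_glass] <- "glass"
  lab[in_cavity & z > geom$fill_height] <- "headspace"
  lab[in_cavity & z <= geom$fill_height] <- "liquid"

  if (include_internals) {
    # Probes: vertical cylinders descending probe_depth from the lid.
    pr <- geom$probe_diameter / 2
    in_probe <- rep(FALSE, length(x))
    for (px in geom$probe_x) {
      in_probe <- in_probe |
        ((x - px)^2 + (y - geom$probe_y)^2 <= pr^2 &
           z >= geom$height - geom$probe_depth & z <= geom$height)
    }
    # Sparger: horizontal tube along x at the bottom, centred.
    sr <- geom$sparger_inlet_diameter / 2
    sx0 <- (geom$width - geom$sparger_length) / 2
    in_sparger <- abs(x - geom$width / 2) <= geom$sparger_length / 2 &
      (y - geom$thickness / 2)^2 + (z - sr)^2 <= sr^2
    # Stirrer zone: cylinder swept by the rotating anchor bar.
    ar <- geom$anchor_length / 2
    in_stir <- (x - geom$width / 2)^2 + (y - geom$thickness / 2)^2 <= ar^2 &
      z >= 0 & z <= geom$anchor_diameter
    lab[in_cavity & in_stir] <- "stirrer_zone"
    lab[in_cavity & in_sparger] <- "sparger"
    lab[in_cavity & in_probe] <- "probe"
  }
  lab
}
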