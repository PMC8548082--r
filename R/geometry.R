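# Sample geometry: planar slabs and spline-profiled cylinders, centred on
# the origin. Coordinates are right-handed with the beam antiparallel to +z
# at zero tilt and the tilt axis along +y; all lengths in Angstroms.

#' Planar (lamella) sample geometry
#'
#' A rectangular slab centred on the origin: `|x| <= x_width/2`,
#' `|y| <= y_width/2`, `|z| <= z_depth/2`. The z depth is the beam-direction
#' thickness at zero tilt.
#'
#' @param x_width,y_width,z_depth Slab dimensions in Angstroms (> 0).
#' @return A `twin_geometry` list.
#' @export
plane_geometry <- function(x_width, y_width, z_depth) {
  stopifnot(x_width > 0, y_width > 0, z_depth > 0)
  structure(list(shape = "plane", x_width = x_width, y_width = y_width,
                 z_depth = z_depth), class = "twin_geometry")
}

#' Cylindrical sample geometry with a spline radius profile
#'
#' A cylinder of given `length` along the tilt axis (+y), centred on the
#' origin. `radius` gives a constant radius; alternatively `profile` is a
#' data.frame with strictly increasing `position` (Angstroms along the axis,
#' relative to the cylinder centre), `radius`, and optional in-plane centre
#' offsets `offset_x`/`offset_z`, all interpolated by natural cubic splines
#' to produce "natural" non-ideal shapes.
#'
#' @param length Cylinder length in Angstroms.
#' @param radius Constant radius (ignored when `profile` is given).
#' @param profile Optional data.frame of spline knots (see Details).
#' @return A `twin_geometry` list.
#' @export
cylinder_geometry <- function(length, radius = NULL, profile = NULL) {
  stopifnot(length > 0)
  if (is.null(profile)) {
    stopifnot(!is.null(radius), radius > 0)
    profile <- data.frame(position = c(-length / 2, length / 2),
                          radius = radius, offset_x = 0, offset_z = 0)
  }
  if (is.null(profile$offset_x)) profile$offset_x <- 0
  if (is.null(profile$offset_z)) profile$offset_z <- 0
  if (any(diff(profile$position) <= 0)) {
    stop("cylinder profile positions must be strictly increasing")
  }
  if (any(profile$radius <= 0)) stop("cylinder profile radii must be > 0")
  g <- list(shape = "cylinder", length = length, profile = profile)
  # constant knots must reproduce an exact cylinder, so use method "natural"
  # (linear outside the knots, exact for constant data)
  g$radius_fun <- stats::splinefun(profile$position, profile$radius,
                                   method = "natural")
  g$offset_x_fun <- stats::splinefun(profile$position, profile$offset_x,
                                     method = "natural")
  g$offset_z_fun <- stats::splinefun(profile$position, profile$offset_z,
                                     method = "natural")
  class(g) <- "twin_geometry"
  g
}

#' Test whether points lie inside a sample geometry
#'
#' @param geom A `twin_geometry`.
#' @param pts An n x 3 matrix of coordinates (Angstroms).
#' @param margin Required clearance from the surface (Angstroms); positive
#'   values shrink the admissible region (used for whole-particle
#'   containment via the bounding radius).
#' @return Logical vector of length n.
#' @export
geometry_contains <- function(geom, pts, margin = 0) {
  pts <- matrix(pts, ncol = 3)
  if (geom$shape == "plane") {
    abs(pts[, 1]) <= geom$x_width / 2 - margin &
      abs(pts[, 2]) <= geom$y_width / 2 - margin &
      abs(pts[, 3]) <= geom$z_depth / 2 - margin
  } else if (geom$shape == "cylinder") {
    t <- pts[, 2]
    inside_len <- abs(t) <= geom$length / 2 - margin
    r <- geom$radius_fun(t)
    dx <- pts[, 1] - geom$offset_x_fun(t)
    dz <- pts[, 3] - geom$offset_z_fun(t)
    inside_len & (dx^2 + dz^2 <= pmax(r - margin, 0)^2)
  } else {
    stop("unknown geometry shape '", geom$shape, "'")
  }
}

#' Volume of a sample geometry
#'
#' Plane volume is exact; cylinder volume integrates the spline radius
#' profile numerically (trapezoid on a 10000-point grid).
#'
#' @param geom A `twin_geometry`.
#' @return Volume in cubic Angstroms.
#' @export
geometry_volume <- function(geom) {
  if (geom$shape == "plane") {
    geom$x_width * geom$y_width * geom$z_depth
  } else {
    t <- seq(-geom$length / 2, geom$length / 2, length.out = 10000)
    a <- pi * geom$radius_fun(t)^2
    sum((a[-1] + a[-length(a)]) / 2) * diff(t[1:2])
  }
}

# Axis-aligned bounding half-extents c(hx, hy, hz) of the geometry
geometry_half_extent <- function(geom) {
  if (geom$shape == "plane") {
    c(geom$x_width, geom$y_width, geom$z_depth) / 2
  } else {
    t <- seq(-geom$length / 2, geom$length / 2, length.out = 512)
    rx <- max(abs(geom$offset_x_fun(t)) + geom$radius_fun(t))
    rz <- max(abs(geom$offset_z_fun(t)) + geom$radius_fun(t))
    c(rx, geom$length / 2, rz)
  }
}

# Beam-frame z half-extent of the geometry when tilted by alpha (radians)
# about +y: used to choose the multislice z-range.
geometry_z_extent <- function(geom, alpha) {
  h <- geometry_half_extent(geom)
  abs(h[1] * sin(alpha)) + abs(h[3] * cos(alpha))
}
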