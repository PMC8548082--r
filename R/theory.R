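# Closed-form geometry and sampling formulas for single-axis tomography of
# planar lamellae and cylinders. All angles in degrees at the interface.

#' Relative projected thickness of a tilted planar sample
#'
#' A planar lamella of zero-tilt thickness \eqn{D_0} presents a path length
#' \eqn{D = D_0 / \cos\alpha} to the beam when tilted by \eqn{\alpha}, so the
#' relative thickness is \eqn{D/D_0 = 1/\cos\alpha}.
#'
#' @param alpha Tilt angle(s) in degrees; must satisfy `abs(alpha) < 90`
#'   (a lamella tilted to 90 degrees presents an unbounded path).
#' @return Relative thickness `1 / cos(alpha)`, dimensionless.
#' @seealso [relative_intensity()], [missing_wedge_angle()]
#' @examples
#' relative_thickness(60) # == 2
#' @export
relative_thickness <- function(alpha) {
  if (any(!is.finite(alpha)) || any(abs(alpha) >= 90)) {
    stop("relative_thickness() requires |alpha| < 90 degrees (planar sample)")
  }
  1 / cos(deg2rad(alpha))
}

#' Relative transmitted intensity of a tilted planar sample
#'
#' Beer-Lambert attenuation through a tilted slab of zero-tilt thickness
#' `d0` with inelastic mean free path `lambda_in` gives
#' \eqn{I/I_0 = \exp((1 - 1/\cos\alpha)\, D_0/\Lambda_{in})}, normalised to
#' the zero-tilt intensity.
#'
#' @inheritParams relative_thickness
#' @param d0 Zero-tilt thickness (any length unit, same as `lambda_in`).
#' @param lambda_in Inelastic mean free path, same unit as `d0`. The symbol
#'   is kept distinct from the electron wavelength.
#' @return Relative intensity in (0, 1].
#' @examples
#' relative_intensity(60, d0 = 150, lambda_in = 314) # exp(-150/314)
#' @export
relative_intensity <- function(alpha, d0, lambda_in) {
  stopifnot(d0 > 0, lambda_in > 0)
  exp((1 - relative_thickness(alpha)) * d0 / lambda_in)
}

#' Crowther resolution criterion
#'
#' Achievable resolution from `n` equally spaced projections of an object of
#' diameter `d_obj`: \eqn{d = \pi D / N}.
#'
#' @param d_obj Object (sample) diameter in Angstroms.
#' @param n Number of projections (>= 1).
#' @return Resolution `pi * d_obj / n` in Angstroms.
#' @examples
#' crowther_resolution(1500, 90)
#' @export
crowther_resolution <- function(d_obj, n) {
  stopifnot(d_obj > 0, n >= 1)
  pi * d_obj / n
}

#' Missing wedge angle of a limited tilt range
#'
#' A single-axis tilt series spanning `(-max_tilt, +max_tilt)` leaves an
#' unsampled wedge of `180 - 2 * max_tilt` degrees in Fourier space.
#'
#' @param max_tilt Maximum tilt angle in degrees, in (0, 90].
#' @return Missing wedge angle in degrees.
#' @examples
#' missing_wedge_angle(60) # 60
#' @export
missing_wedge_angle <- function(max_tilt) {
  stopifnot(max_tilt > 0, max_tilt <= 90)
  180 - 2 * max_tilt
}

#' Tabulate tilt-geometry theory over a parameter grid
#'
#' Convenience table of relative thickness, relative intensity and Crowther
#' resolution over tilt angles and projection counts; used by the
#' command-line interface.
#'
#' @param alpha Tilt angles, degrees (|alpha| < 90).
#' @param d0 Zero-tilt thickness, nm (converted consistently with
#'   `lambda_in`).
#' @param lambda_in Inelastic mean free path, nm.
#' @param d_obj Sample diameter in Angstroms for the Crowther criterion.
#' @param n Projection counts.
#' @return A data.frame with one row per (alpha, n) combination.
#' @export
theory_table <- function(alpha = seq(0, 85, by = 5), d0 = 150,
                         lambda_in = 314, d_obj = 1500, n = 90) {
  grid <- expand.grid(alpha = alpha, n = n)
  data.frame(
    alpha = grid$alpha,
    n = grid$n,
    relative_thickness = relative_thickness(grid$alpha),
    relative_intensity = relative_intensity(grid$alpha, d0, lambda_in),
    crowther_d = crowther_resolution(d_obj, grid$n),
    missing_wedge = ifelse(grid$alpha <= 90, 180 - 2 * grid$alpha, NA_real_)
  )
}
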