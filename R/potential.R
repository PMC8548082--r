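# Projected electrostatic potential of the specimen on a multislice grid.
#
# Each atom deposits an integrated projected potential proportional to its
# atomic number (amplitude `atom_amplitude` V*A^3 per unit Z, default 30),
# shaped as an isotropic Gaussian of width `atom_sigma` (default 1.0 A).
# This single-Gaussian parameterisation is deliberately simple and pluggable
# (see the methods vignette); slice values are in V*A (potential integrated
# through the slice).

# Gaussian in-plane kernel times optional damage filter, in Fourier space
slice_filter <- function(nx, ny, pixel, sigma, damage_b = 0) {
  q2 <- freq_grid2(nx, ny, pixel)^2
  h <- exp(-2 * pi^2 * sigma^2 * q2)
  if (damage_b > 0) h <- h * exp(-q2 * damage_b / 4)
  h
}

#' Grid specification for projection and imaging
#'
#' @param nx,ny Lateral grid size in pixels.
#' @param pixel Pixel size in Angstroms.
#' @param slice_thickness Multislice slice thickness in Angstroms.
#' @return A list used by [project_potential()] and the imaging chain.
#' @export
grid_spec <- function(nx, ny, pixel = 1, slice_thickness = 5) {
  stopifnot(nx >= 1, ny >= 1, pixel > 0, slice_thickness > 0)
  list(nx = as.integer(nx), ny = as.integer(ny), pixel = pixel,
       slice_thickness = slice_thickness)
}

#' Project a sample's potential onto multislice slices at a tilt angle
#'
#' Rotates the sample by the tilt angle about the +y axis into the beam
#' frame, divides the beam path into slices of `grid$slice_thickness`, and
#' accumulates per-slice projected potential: the atomic contributions of
#' all particles (plus random-water ice atoms), and the Gaussian-random-field
#' ice sampled as a continuum contribution integrated over each slice.
#'
#' The beam-damage filter `exp(-q^2 B / 4)` is a Gaussian, so for the
#' Gaussian atom profile it is folded analytically into the deposited atom
#' width (`sigma_eff^2 = atom_sigma^2 + B / (8 pi^2)`), which is exactly the
#' composition with [apply_beam_damage()] for the atomic potential. The
#' continuum ice field is treated as already-damaged background: its
#' correlation length is a phenomenological input and is not re-filtered per
#' image (see the methods vignette).
#'
#' @param sample A `twin_sample`.
#' @param tilt Tilt angle in degrees.
#' @param grid A [grid_spec()].
#' @param damage_b Beam-damage B factor in A^2 (see [apply_beam_damage()]).
#' @param offset Optional length-2 beam-frame lateral shift (A) applied to
#'   the sample, used for beam drift / stage translation.
#' @param atom_amplitude Integrated projected potential per unit atomic
#'   number, V*A^3.
#' @param atom_sigma Gaussian atom width, Angstroms.
#' @return A `potential_slices` object: 3D array `slices` (nx x ny x nz,
#'   V*A), `interior` (fraction of each slice voxel inside the sample
#'   geometry), `pixel`, `slice_thickness`, `z0` (beam-frame z of the first
#'   slice centre) and `clipped` (number of atoms outside the lateral grid).
#' @export
project_potential <- function(sample, tilt, grid, damage_b = 0,
                              offset = c(0, 0), atom_amplitude = 30,
                              atom_sigma = 1.0) {
  alpha <- deg2rad(tilt)
  ts <- grid$slice_thickness
  zmax <- geometry_z_extent(sample$geometry, alpha)
  nz <- max(1L, as.integer(ceiling(2 * zmax / ts)))
  z0 <- -(nz / 2 - 0.5) * ts # beam-frame z of first slice centre
  nx <- grid$nx; ny <- grid$ny; px <- grid$pixel
  ca <- cos(alpha); sa <- sin(alpha)

  vol <- array(0, c(nx, ny, nz))
  clipped <- 0L
  atom_slices <- integer(0)
  atoms <- sample_atoms(sample, include_ice = TRUE)
  if (nrow(atoms) > 0) {
    # sample frame -> beam frame: rotate about +y by tilt, then shift
    xb <- atoms$x * ca + atoms$z * sa + offset[1]
    yb <- atoms$y + offset[2]
    zb <- -atoms$x * sa + atoms$z * ca
    # bilinear in-plane deposition (cloud-in-cell): the same triangle kernel
    # at every tilt, so no tilt-dependent quantisation jitter enters the
    # projections; the slice index is nearest-bin (the projection integrates
    # over z within a slice)
    gx0 <- xb / px + nx / 2 + 1 # continuous grid index; node nx/2+1 is x = 0
    gy0 <- yb / px + ny / 2 + 1
    ix <- floor(gx0); fx <- gx0 - ix
    iy <- floor(gy0); fy <- gy0 - iy
    iz <- pmin(pmax(floor((zb - z0 + ts / 2) / ts) + 1, 1L), nz)
    ok <- ix >= 1 & ix < nx & iy >= 1 & iy < ny
    clipped <- sum(!ok)
    if (clipped > 0) {
      warning(clipped, " atom(s) outside the lateral grid were clipped")
    }
    amp <- lookup_z(atoms$element[ok]) * atoms$occupancy[ok] *
      atom_amplitude / px^2
    ixo <- ix[ok]; iyo <- iy[ok]; izo <- iz[ok]
    fxo <- fx[ok]; fyo <- fy[ok]
    base <- (izo - 1L) * (nx * ny)
    idx <- c(base + (iyo - 1L) * nx + ixo,
             base + (iyo - 1L) * nx + ixo + 1L,
             base + iyo * nx + ixo,
             base + iyo * nx + ixo + 1L)
    w <- c(amp * (1 - fxo) * (1 - fyo), amp * fxo * (1 - fyo),
           amp * (1 - fxo) * fyo, amp * fxo * fyo)
    acc <- rowsum(w, idx)
    vol[as.integer(rownames(acc))] <- acc
    atom_slices <- sort(unique(izo))
    # atom shape with the damage blur folded in analytically
    sigma_eff <- sqrt(atom_sigma^2 + damage_b / (8 * pi^2))
    h <- slice_filter(nx, ny, px, sigma_eff)
    for (k in atom_slices) {
      vol[, , k] <- fourier_filter(vol[, , k], h)
    }
  }

  # interior mask and continuum GRF ice, sampled at slice-centre beam-frame
  # coordinates rotated back into the sample frame
  interior <- array(0, c(nx, ny, nz))
  grf <- identical(sample$ice$model, "grf")
  if (grf && is.null(sample$ice$field)) {
    half <- geometry_half_extent(sample$geometry)
    shape <- pmax(8L, as.integer(ceiling(2 * half / sample$ice$voxel)) + 4L)
    sample$ice$field <- ice_grf(shape, sample$ice$voxel, sample$ice$mean,
                                sample$ice$variance,
                                sample$ice$correlation_length,
                                sample$ice$seed)
  }
  gx <- grid_axis(nx, px); gy <- grid_axis(ny, px)
  xg <- rep(gx, times = ny) - offset[1]
  yg <- rep(gy, each = nx) - offset[2]
  half_ext <- geometry_half_extent(sample$geometry)
  fov_r <- max(abs(gx)) + px + abs(offset[1])
  for (k in seq_len(nz)) {
    zk <- z0 + (k - 1) * ts
    # cheap reject: can any FOV column intersect the geometry at this slice?
    # sample-frame (x, z) of the slice lies on a line at distance |zk| from
    # the origin; skip when outside the bounding box by more than the FOV
    xs_c <- -zk * sa; zs_c <- zk * ca
    if (abs(xs_c) > half_ext[1] + fov_r || abs(zs_c) > half_ext[3] + fov_r) next
    xs <- xg * ca - zk * sa # beam frame -> sample frame (rotate by -tilt)
    zs <- xg * sa + zk * ca
    ins <- geometry_contains(sample$geometry, cbind(xs, yg, zs))
    if (!any(ins)) next
    interior[, , k] <- ins
    if (grf) {
      f <- trilinear(sample$ice$field, xs, yg, zs,
                     attr(sample$ice$field, "voxel"))
      vol[, , k] <- vol[, , k] + f * ins * ts # V*A, integrated over the slice
    }
  }

  structure(
    list(slices = vol, pixel = px, slice_thickness = ts, z0 = z0,
         interior = interior, clipped = clipped),
    class = "potential_slices"
  )
}

#' Apply the dose-dependent beam-damage filter to a potential
#'
#' Radiation damage is modelled as an isotropic Gaussian blurring of the
#' specimen potential with B factor linear in the accumulated electron dose:
#' `B = 8 * pi^2 * dose * sensitivity`. Each slice is filtered in Fourier
#' space by `exp(-q^2 B / 4)`; the q = 0 component (slice mean) is
#' preserved.
#'
#' @param potential A `potential_slices` object.
#' @param dose Accumulated electron dose D_E, e-/A^2.
#' @param sensitivity Damage sensitivity coefficient S_E, A^2/e- (default
#'   0.022; typical calibrated values are 0.020-0.090).
#' @return The filtered `potential_slices`.
#' @export
apply_beam_damage <- function(potential, dose, sensitivity = 0.022) {
  stopifnot(dose >= 0, sensitivity >= 0)
  b <- damage_b_factor(dose, sensitivity)
  if (b == 0) return(potential)
  dm <- dim(potential$slices)
  h <- slice_filter(dm[1], dm[2], potential$pixel, 0, b)
  for (k in seq_len(dm[3])) {
    if (any(potential$slices[, , k] != 0)) {
      potential$slices[, , k] <- fourier_filter(potential$slices[, , k], h)
    }
  }
  potential
}

#' Beam-damage B factor at an accumulated dose
#'
#' @inheritParams apply_beam_damage
#' @return `8 * pi^2 * dose * sensitivity`, in A^2.
#' @export
damage_b_factor <- function(dose, sensitivity = 0.022) {
  8 * pi^2 * dose * sensitivity
}

#' Render an atomic model as a real-space density volume
#'
#' Deposits the same per-atom integrated potential used by the imaging chain
#' (amplitude proportional to Z, Gaussian width `atom_sigma`) on a cubic
#' grid. Used as the ground-truth reference when closing the loop with
#' Fourier shell correlation.
#'
#' @param model An `atomic_model` (coordinates relative to the volume
#'   centre).
#' @param shape Integer grid dimensions, e.g. `c(64, 64, 64)`.
#' @param voxel Voxel size in Angstroms.
#' @param atom_amplitude,atom_sigma As in [project_potential()].
#' @return A `twin_volume`: 3D array with `voxel` attribute.
#' @export
render_density <- function(model, shape, voxel, atom_amplitude = 30,
                           atom_sigma = 1.0) {
  shape <- as.integer(shape)
  vol <- array(0, shape)
  # trilinear (cloud-in-cell) deposition, matching the projection chain
  gx <- model$x / voxel + shape[1] / 2 + 1
  gy <- model$y / voxel + shape[2] / 2 + 1
  gz <- model$z / voxel + shape[3] / 2 + 1
  ix <- floor(gx); fx <- gx - ix
  iy <- floor(gy); fy <- gy - iy
  iz <- floor(gz); fz <- gz - iz
  ok <- ix >= 1 & ix < shape[1] & iy >= 1 & iy < shape[2] &
    iz >= 1 & iz < shape[3]
  amp <- lookup_z(model$element[ok]) * model$occupancy[ok] *
    atom_amplitude / voxel^3
  ixo <- ix[ok]; iyo <- iy[ok]; izo <- iz[ok]
  fxo <- fx[ok]; fyo <- fy[ok]; fzo <- fz[ok]
  nxy <- shape[1] * shape[2]
  corner <- function(dx, dy, dz) {
    idx <- (izo - 1L + dz) * nxy + (iyo - 1L + dy) * shape[1] + ixo + dx
    wt <- amp * (if (dx == 0) 1 - fxo else fxo) *
      (if (dy == 0) 1 - fyo else fyo) * (if (dz == 0) 1 - fzo else fzo)
    list(idx = idx, wt = wt)
  }
  parts <- list(corner(0, 0, 0), corner(1, 0, 0), corner(0, 1, 0),
                corner(1, 1, 0), corner(0, 0, 1), corner(1, 0, 1),
                corner(0, 1, 1), corner(1, 1, 1))
  acc <- rowsum(unlist(lapply(parts, `[[`, "wt")),
                unlist(lapply(parts, `[[`, "idx")))
  vol[as.integer(rownames(acc))] <- acc
  g <- freq_grid3(shape, voxel)
  vol <- Re(ifft(stats::fft(vol) * exp(-2 * pi^2 * atom_sigma^2 * g$q^2)))
  structure(vol, voxel = voxel, class = c("twin_volume", "array"))
}
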