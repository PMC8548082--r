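# Reconstruction: CTF correction by phase flipping, gap-weighted filtered
# back projection about the y tilt axis, and per-particle subvolume
# reconstruction at the particle-centre defocus.

#' Correct contrast inversions by phase flipping
#'
#' Multiplies the image's Fourier transform by the sign of the
#' phase-contrast transfer `sin(chi + phi_pp) * envelope`; zeros of the
#' transfer (a measure-zero set including DC when no phase plate is present)
#' are left unchanged (sign treated as +1), so applying the correction twice
#' is the identity.
#'
#' @param image Real image matrix.
#' @param ctf A `twin_ctf` evaluated on the same grid.
#' @return The corrected real image.
#' @export
phase_flip <- function(image, ctf) {
  if (!all(dim(image) == dim(ctf$q))) {
    stop("image and CTF grids do not match")
  }
  s <- sign(ctf$imag)
  s[s == 0] <- 1
  Re(ifft(stats::fft(image) * s))
}

# Local angular gap weights (radians) for a sorted angle set: the average of
# the two adjacent gaps, with end gaps reflected. Equal spacing reduces to
# the classical ramp normalisation (sum of weights = angular span + one gap).
angular_gap_weights <- function(angles_deg) {
  a <- deg2rad(sort(angles_deg))
  n <- length(a)
  if (n == 1) return(pi)
  d <- diff(a)
  w <- numeric(n)
  w[1] <- d[1]
  w[n] <- d[n - 1]
  if (n > 2) w[2:(n - 1)] <- (d[-length(d)] + d[-1]) / 2
  w
}

# 1D ramp filter along the first dimension, FFT order, in cycles/A. Uses
# the discrete band-limited (Ram-Lak) kernel rather than a plain |q|: the
# discrete kernel h(0) = 1/(4 d^2), h(n) = -1/(pi^2 n^2 d^2) for odd n,
# 0 for even n has the correct low-frequency response on a sampled grid
# (a plain |q| ramp suppresses the lowest frequencies and digs a negative
# halo around reconstructed objects).
ramp_filter <- function(nx, pixel) {
  m <- c(seq.int(0L, floor((nx - 1) / 2)), seq.int(-floor(nx / 2), -1L))
  h <- numeric(nx)
  h[m == 0] <- 1 / (4 * pixel^2)
  odd <- m %% 2 != 0
  h[odd] <- -1 / (pi^2 * m[odd]^2 * pixel^2)
  Re(stats::fft(h)) * pixel
}

# Sparse bilinear back-projection operator for one tilt angle: maps a
# projection P (nxp x nyp) onto box voxels via two separable interpolation
# matrices, value(u) = (Wxz %*% P %*% t(Wy))[u]. `centre` is the particle
# centre in the sample frame; box voxel offsets are u (box grid, A). Voxels
# whose projection falls outside the image receive no contribution from
# that angle.
bp_operators <- function(angle_deg, box, voxel, nxp, nyp, pixel, centre = c(0, 0, 0)) {
  alpha <- deg2rad(angle_deg)
  ux <- grid_axis(box[1], voxel)
  uy <- grid_axis(box[2], voxel)
  uz <- grid_axis(box[3], voxel)
  # sparse linear-interpolation matrix mapping grid columns to coordinates
  interp1 <- function(coord, npix) {
    g <- coord / pixel + npix %/% 2 + 1 # continuous 1-based grid index
    i0 <- floor(g); f <- g - i0
    rows <- rep(seq_along(g), 2)
    cols <- c(i0, i0 + 1)
    vals <- c(1 - f, f)
    keep <- cols >= 1 & cols <= npix & vals > 0
    Matrix::sparseMatrix(i = rows[keep], j = cols[keep], x = vals[keep],
                         dims = c(length(g), npix))
  }
  # beam-frame lateral coordinate of each (x, z) voxel column
  xp <- outer(ux + centre[1], uz + centre[3],
              function(x, z) x * cos(alpha) + z * sin(alpha))
  list(wxz = interp1(as.vector(xp), nxp),
       wy = interp1(uy + centre[2], nyp))
}

#' Weighted back projection about the y tilt axis
#'
#' Filters each projection with a one-dimensional ramp along the direction
#' perpendicular to the tilt axis, scaled by the projection's local angular
#' gap (the mean of its two neighbouring tilt increments, in radians), and
#' back-projects with bilinear interpolation. For uniformly spaced angles
#' the per-projection weights reduce to the classical ramp normalisation
#' `pi / N` over 180 degrees.
#'
#' @param projections Array nx x ny x N of (CTF-corrected, zero-mean
#'   contrast) projections.
#' @param angles Tilt angles in degrees, one per projection.
#' @param shape Output volume dimensions `c(nx, ny, nz)`.
#' @param pixel Projection pixel size (A).
#' @param voxel Output voxel size (A); defaults to `pixel`.
#' @param centre Volume centre in the sample frame (A).
#' @return A `twin_volume` array with a `voxel` attribute.
#' @export
wbp_reconstruct <- function(projections, angles, shape, pixel,
                            voxel = pixel, centre = c(0, 0, 0)) {
  dm <- dim(projections)
  if (length(angles) != dm[3]) stop("one projection per angle required")
  if (length(angles) < 2) stop("weighted back projection needs >= 2 projections")
  shape <- as.integer(shape)
  ord <- order(angles)
  w <- angular_gap_weights(angles)
  ramp <- ramp_filter(dm[1], pixel)
  vol_flat <- matrix(0, shape[1] * shape[3], shape[2])
  for (j in seq_along(ord)) {
    k <- ord[j]
    p <- matrix(projections[, , k], dm[1], dm[2])
    pf <- Re(stats::mvfft(stats::mvfft(p) * ramp, inverse = TRUE)) / dm[1]
    op <- bp_operators(angles[k], shape, voxel, dm[1], dm[2], pixel)
    vol_flat <- vol_flat + w[j] * as.matrix(op$wxz %*% pf %*% Matrix::t(op$wy))
  }
  # flat layout is (x, z) x y; reorder to (x, y, z)
  vol <- aperm(array(vol_flat, c(shape[1], shape[3], shape[2])), c(1, 3, 2))
  structure(vol, voxel = voxel, class = c("twin_volume", "array"))
}

#' Reconstruct per-particle subvolumes from a tilt series
#'
#' For every particle in the ground-truth sample: converts counts to
#' zero-mean contrast, phase-flips each projection at the particle-centre
#' defocus for that tilt (nominal defocus plus the particle's beam-frame
#' z offset, underfocus positive), and runs a weighted back projection into
#' a box centred on the particle. Particles whose reconstructable region
#' (the box's inscribed sphere) projects outside the image field of view at
#' any tilt are skipped and counted; box corner voxels that individual
#' oblique projections cannot see simply receive no contribution from those
#' projections.
#'
#' @param ts A `tilt_series`.
#' @param sample The `twin_sample` that was imaged (known poses).
#' @param box Box size in voxels (scalar or length 3).
#' @param voxel Box voxel size (A); defaults to the image pixel.
#' @return List with `boxes` (list of `twin_volume`), `poses` (data.frame of
#'   the reconstructed particles), and `skipped` (count).
#' @export
extract_subvolumes <- function(ts, sample, box = 64, voxel = NULL) {
  stopifnot(inherits(ts, "tilt_series"))
  box <- rep(as.integer(box), length.out = 3)
  voxel <- voxel %||% ts$pixel
  contrast <- tilt_contrast(ts)
  dm <- dim(contrast)
  angles <- ts$meta$angle
  cfg <- ts$config
  w <- angular_gap_weights(angles)
  ord <- order(angles)
  ramp <- ramp_filter(dm[1], ts$pixel)

  boxes <- list()
  poses <- sample$particles[0, ]
  skipped <- 0L
  for (i in seq_len(nrow(sample$particles))) {
    p <- sample$particles[i, ]
    centre <- c(p$x, p$y, p$z)
    # coverage: the box's inscribed sphere must project inside the image at
    # every tilt; the worst-case lateral offset over tilts about y is the
    # in-plane radius of the particle centre
    rad <- min(box) / 2 * voxel
    lat <- sqrt(p$x^2 + p$z^2) + rad
    ver <- abs(p$y) + rad
    if (lat > dm[1] / 2 * ts$pixel || ver > dm[2] / 2 * ts$pixel) {
      skipped <- skipped + 1L
      next
    }
    ops <- lapply(angles, function(a) {
      bp_operators(a, box, voxel, dm[1], dm[2], ts$pixel, centre)
    })
    vol_flat <- matrix(0, box[1] * box[3], box[2])
    for (j in seq_along(ord)) {
      k <- ord[j]
      alpha <- deg2rad(angles[k])
      # beam-frame z offset of the particle centre at this tilt
      zb <- -p$x * sin(alpha) + p$z * cos(alpha)
      ctf <- ctf_evaluate(cfg$lens, cfg$beam, dm[1], dm[2], ts$pixel,
                          defocus = cfg$lens$defocus + zb)
      img <- phase_flip(contrast[, , k], ctf)
      pf <- Re(stats::mvfft(stats::mvfft(img) * ramp, inverse = TRUE)) / dm[1]
      vol_flat <- vol_flat + w[j] *
        as.matrix(ops[[k]]$wxz %*% pf %*% Matrix::t(ops[[k]]$wy))
    }
    vol <- aperm(array(vol_flat, c(box[1], box[3], box[2])), c(1, 3, 2))
    boxes[[length(boxes) + 1]] <-
      structure(vol, voxel = voxel, class = c("twin_volume", "array"))
    poses <- rbind(poses, p)
  }
  list(boxes = boxes, poses = poses, skipped = skipped)
}
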