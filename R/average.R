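# Missing-wedge masks, volume rotation and wedge-masked subtomogram
# averaging in Fourier space.

#' Missing-wedge Fourier mask for a single-axis tilt range
#'
#' Marks the Fourier-space region sampled by projections over
#' `(-max_tilt, +max_tilt)` about the y axis: an element with frequency
#' components (qx, qy, qz) is sampled when the in-plane direction angle
#' `atan2(|qz|, |qx|)` is at most `max_tilt` (qy is unconstrained, so the
#' mask is invariant along the rotation axis). An optional cosine-tapered
#' soft edge of `soft` degrees can be applied.
#'
#' @param max_tilt Maximum tilt in degrees, in (0, 90]; 90 samples all of
#'   Fourier space.
#' @param shape Mask dimensions `c(nx, ny, nz)`.
#' @param soft Soft-edge width in degrees (0 = binary mask).
#' @return A 3D array in [0, 1], FFT element order, class `wedge_mask`.
#' @export
wedge_mask <- function(max_tilt, shape, soft = 0) {
  stopifnot(max_tilt > 0, max_tilt <= 90)
  shape <- as.integer(shape)
  g <- freq_grid3(shape, 1)
  phi <- rad2deg(atan2(abs(g$qz), abs(g$qx))) # in [0, 90]
  m <- if (soft > 0) {
    pmin(pmax((max_tilt + soft / 2 - phi) / soft, 0), 1)
  } else {
    (phi <= max_tilt) * 1
  }
  m[1, , 1] <- 1 # the qx = qz = 0 line (DC and pure-qy) is always sampled
  structure(array(m, shape), max_tilt = max_tilt, class = c("wedge_mask", "array"))
}

#' Rotate a volume by a quaternion
#'
#' Resamples `vol` with trilinear interpolation so that features rotated by
#' `q` in the original volume appear in the reference orientation:
#' `out(r) = vol(R(q) r)`. Used to align particle boxes (whose contents are
#' the model rotated by the particle orientation) back to the model frame.
#'
#' @param vol 3D array (cubic voxels, centred per the package convention).
#' @param q Unit quaternion c(w, x, y, z), the particle orientation.
#' @return Rotated array of the same shape.
#' @export
rotate_volume <- function(vol, q) {
  if (all(abs(q - quat_identity()) < 1e-12)) return(vol)
  dm <- dim(vol)
  rot <- quat_to_matrix(quat_normalize(q))
  ax <- grid_axis(dm[1], 1); ay <- grid_axis(dm[2], 1); az <- grid_axis(dm[3], 1)
  x <- rep(ax, times = dm[2] * dm[3])
  y <- rep(rep(ay, each = dm[1]), times = dm[3])
  z <- rep(az, each = dm[1] * dm[2])
  pts <- cbind(x, y, z) %*% t(rot) # R(q) r for each output voxel r
  out <- trilinear(vol, pts[, 1], pts[, 2], pts[, 3], 1)
  array(out, dm)
}

# Wedge mask expressed in a rotated particle's reference frame: sampled
# directions are fixed in the beam/world frame, so the mask seen by the
# rotated-back box is wedge(R(q) q_vec).
rotated_wedge_mask <- function(max_tilt, shape, q) {
  if (all(abs(q - quat_identity()) < 1e-12)) return(wedge_mask(max_tilt, shape))
  g <- freq_grid3(as.integer(shape), 1)
  rot <- quat_to_matrix(quat_normalize(q))
  qx <- rot[1, 1] * g$qx + rot[1, 2] * g$qy + rot[1, 3] * g$qz
  qz <- rot[3, 1] * g$qx + rot[3, 2] * g$qy + rot[3, 3] * g$qz
  phi <- rad2deg(atan2(abs(qz), abs(qx)))
  m <- (phi <= max_tilt) * 1
  m[1, 1, 1] <- 1
  structure(m, max_tilt = max_tilt, class = c("wedge_mask", "array"))
}

#' Wedge-masked subtomogram averaging with known poses
#'
#' Rotates each particle box to the reference orientation, multiplies its
#' Fourier transform by the correspondingly rotated missing-wedge mask, sums
#' the masked transforms and divides by the summed mask with a Wiener-style
#' floor (`eps` times the maximum summed mask). Regions never covered by any
#' wedge are zero-filled and reported.
#'
#' @param boxes List of 3D arrays (equal shapes), e.g. from
#'   [extract_subvolumes()].
#' @param poses Data.frame with quaternion columns `qw`, `qx`, `qy`, `qz`
#'   (one row per box), or NULL for identity orientations.
#' @param max_tilt Tilt range that produced the boxes (degrees), defining
#'   the wedge mask; 90 for full coverage.
#' @param eps Wiener floor as a fraction of the maximum summed mask.
#' @return A `twin_volume` with attributes `coverage` (summed mask fraction
#'   > 0) and `uncovered` (number of zero-filled Fourier elements).
#' @export
subtomogram_average <- function(boxes, poses = NULL, max_tilt = 90,
                                eps = 1e-3) {
  stopifnot(length(boxes) >= 1)
  dm <- dim(boxes[[1]])
  acc <- array(0 + 0i, dm)
  msum <- array(0, dm)
  for (i in seq_along(boxes)) {
    q <- if (is.null(poses)) quat_identity() else
      unlist(poses[i, c("qw", "qx", "qy", "qz")], use.names = FALSE)
    aligned <- rotate_volume(boxes[[i]], q)
    m <- rotated_wedge_mask(max_tilt, dm, q)
    acc <- acc + stats::fft(aligned) * m
    msum <- msum + m
  }
  uncovered <- sum(msum == 0)
  floorv <- eps * max(msum)
  avg_f <- acc / pmax(msum, floorv)
  avg_f[msum == 0] <- 0
  out <- Re(ifft(avg_f))
  voxel <- attr(boxes[[1]], "voxel") %||% 1
  structure(array(out, dm), voxel = voxel,
            coverage = mean(msum > 0), uncovered = uncovered,
            class = c("twin_volume", "array"))
}
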