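# Fourier conventions used throughout the package:
#  * forward transform kernel exp(-2*pi*1i*q*x) (stats::fft), inverse scaled
#    by 1/N;
#  * frequency grids in inverse Angstroms, laid out in native FFT order
#    (DC first, then positive, then negative frequencies).

#' FFT-order frequency axis
#'
#' Frequencies (cycles per Angstrom) associated with an `n`-point grid of
#' spacing `d` Angstroms, in the native output order of [stats::fft()].
#'
#' @param n Number of grid points.
#' @param d Grid spacing in Angstroms.
#' @return Numeric vector of length `n`, units 1/Angstrom.
#' @export
fft_freq <- function(n, d = 1) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

# 2D |q| grid (nx x ny) in 1/Angstrom, FFT order
freq_grid2 <- function(nx, ny, d) {
  qx <- fft_freq(nx, d)
  qy <- fft_freq(ny, d)
  sqrt(outer(qx^2, qy^2, "+"))
}

# list(qx, qy, qz, q) of 3D frequency component arrays, FFT order
freq_grid3 <- function(shape, d) {
  qx <- fft_freq(shape[1], d)
  qy <- fft_freq(shape[2], d)
  qz <- fft_freq(shape[3], d)
  ax <- array(qx, shape)
  ay <- array(rep(qy, each = shape[1]), shape)
  az <- array(rep(qz, each = shape[1] * shape[2]), shape)
  list(qx = ax, qy = ay, qz = az, q = sqrt(ax^2 + ay^2 + az^2))
}

ifft <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Apply a real Fourier-domain filter H (same shape, FFT order) to a real
# array; returns a real array.
fourier_filter <- function(x, h) {
  Re(ifft(stats::fft(x) * h))
}

# Centred coordinate axis for an n-point grid of spacing d: grid point i has
# coordinate (i - 1 - n/2) * d so that index n/2 + 1 sits at 0.
grid_axis <- function(n, d) (seq_len(n) - 1 - n %/% 2) * d

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- quaternions -----------------------------------------------------------

# Quaternions are length-4 numeric vectors c(w, x, y, z), unit norm.

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_identity <- function() c(1, 0, 0, 0)

# 3x3 rotation matrix of a unit quaternion (active rotation)
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# Uniform random unit quaternions (Shoemake's method); n x 4 matrix
quat_random <- function(n) {
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  cbind(
    sqrt(1 - u1) * sin(2 * pi * u2),
    sqrt(1 - u1) * cos(2 * pi * u2),
    sqrt(u1) * sin(2 * pi * u3),
    sqrt(u1) * cos(2 * pi * u3)
  )[, c(1, 2, 3, 4), drop = FALSE]
}

# Rotation matrix about +y by alpha (radians), column-vector convention
rot_y <- function(alpha) {
  ca <- cos(alpha); sa <- sin(alpha)
  matrix(c(ca, 0, sa, 0, 1, 0, -sa, 0, ca), 3, 3, byrow = TRUE)
}

# --- trilinear interpolation ----------------------------------------------

# Sample a 3D array `vol` (grid centred per grid_axis with spacing d) at
# coordinates (x, y, z) in Angstroms. Points outside return `fill`.
trilinear <- function(vol, x, y, z, d, fill = 0) {
  dm <- dim(vol)
  gx <- x / d + dm[1] %/% 2 + 1
  gy <- y / d + dm[2] %/% 2 + 1
  gz <- z / d + dm[3] %/% 2 + 1
  i0 <- floor(gx); j0 <- floor(gy); k0 <- floor(gz)
  fx <- gx - i0; fy <- gy - j0; fz <- gz - k0
  ok <- i0 >= 1 & i0 < dm[1] & j0 >= 1 & j0 < dm[2] & k0 >= 1 & k0 < dm[3]
  out <- rep(fill, length(x))
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  nxy <- dm[1] * dm[2]
  base <- (k0 - 1) * nxy + (j0 - 1) * dm[1] + i0
  v000 <- vol[base];             v100 <- vol[base + 1]
  v010 <- vol[base + dm[1]];     v110 <- vol[base + dm[1] + 1]
  v001 <- vol[base + nxy];       v101 <- vol[base + nxy + 1]
  v011 <- vol[base + nxy + dm[1]]; v111 <- vol[base + nxy + dm[1] + 1]
  out[ok] <-
    (1 - fz) * ((1 - fy) * ((1 - fx) * v000 + fx * v100) +
                  fy * ((1 - fx) * v010 + fx * v110)) +
    fz * ((1 - fy) * ((1 - fx) * v001 + fx * v101) +
            fy * ((1 - fx) * v011 + fx * v111))
  out
}

# Derive a reproducible sub-seed (< 2^31) from a base seed and stream index
derive_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 1000003) * 2011 + as.numeric(k) * 7919
  as.integer(s %% 2147483647)
}
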