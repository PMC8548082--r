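# Fourier shell correlation and its element-count-weighted average, with
# optional restriction to resolution bands or reciprocal planes.

#' Fourier shell correlation between two volumes
#'
#' `FSC_i = Re<F_a F_b*>_i / sqrt(<|F_a|^2>_i <|F_b|^2>_i)` over shells one
#' Fourier voxel wide; the element count `N_i` of every shell is recorded.
#' Shells where either volume has zero power yield NA (recorded, not
#' dropped). An optional element mask restricts the correlation to a subset
#' of Fourier elements (used for plane-restricted anisotropy measures).
#'
#' @param vol_a,vol_b 3D arrays on the same grid.
#' @param voxel Voxel size (A); taken from `vol_a` when available.
#' @param mask Optional logical/numeric array selecting Fourier elements
#'   (FFT order).
#' @return An `fsc_curve` data.frame with columns `shell` (index), `q`
#'   (shell centre, 1/A), `fsc` and `n`.
#' @export
fsc <- function(vol_a, vol_b, voxel = NULL, mask = NULL) {
  if (!all(dim(vol_a) == dim(vol_b))) stop("volumes must share a grid")
  voxel <- voxel %||% attr(vol_a, "voxel") %||% 1
  dm <- dim(vol_a)
  fa <- stats::fft(array(as.numeric(vol_a), dm))
  fb <- stats::fft(array(as.numeric(vol_b), dm))
  # shell index: |q| in units of the smallest frequency step
  g <- freq_grid3(dm, 1) # voxel-normalised frequencies, cycles/voxel
  shell <- as.integer(round(g$q * min(dm))) + 1L
  keep <- g$q <= 0.5 # up to Nyquist
  if (!is.null(mask)) keep <- keep & (mask != 0)
  shell <- shell[keep]
  cross <- Re(fa * Conj(fb))[keep]
  pa <- Mod(fa)[keep]^2
  pb <- Mod(fb)[keep]^2
  num <- rowsum(cross, shell)
  da <- rowsum(pa, shell)
  db <- rowsum(pb, shell)
  n <- as.vector(rowsum(rep(1, length(shell)), shell))
  denom <- sqrt(da * db)
  vals <- ifelse(denom > 0, num / denom, NA_real_)
  idx <- as.integer(rownames(num))
  structure(
    data.frame(shell = idx, q = (idx - 1) / (min(dm) * voxel),
               fsc = as.vector(vals), n = n),
    class = c("fsc_curve", "data.frame")
  )
}

#' Element-count-weighted FSC average
#'
#' The weighted mean `sum(N_i FSC_i) / sum(N_i)` over the selected shells,
#' where `N_i` is the number of Fourier elements in shell i. Selection can
#' be all shells, a resolution band (`"low"`/`"high"`, split at half the
#' Nyquist frequency by default), or an explicit shell filter.
#'
#' @param curve An `fsc_curve` from [fsc()].
#' @param selection `"all"`, `"low"`, `"high"`, or a logical vector/function
#'   of the shell centre frequency `q`.
#' @param split Band boundary as a fraction of Nyquist (default 0.5).
#' @return The weighted mean FSC (scalar). NA shells are excluded from both
#'   sums; an empty selection is an error.
#' @export
fsc_average <- function(curve, selection = "all", split = 0.5) {
  qn <- max(curve$q) # highest shell centre ~ Nyquist
  sel <- if (is.function(selection)) {
    selection(curve$q)
  } else if (identical(selection, "all")) {
    rep(TRUE, nrow(curve))
  } else if (identical(selection, "low")) {
    curve$q < split * qn
  } else if (identical(selection, "high")) {
    curve$q >= split * qn
  } else if (is.logical(selection)) {
    selection
  } else {
    stop("unknown FSC selection")
  }
  sel <- sel & !is.na(curve$fsc)
  if (!any(sel)) stop("empty FSC shell selection")
  sum(curve$n[sel] * curve$fsc[sel]) / sum(curve$n[sel])
}

#' Reciprocal-plane element mask for anisotropic FSC
#'
#' Selects Fourier elements whose direction lies within `half_angle` degrees
#' of the named reciprocal plane (an angular slab; the convention is
#' declared in outputs that use it).
#'
#' @param shape Volume dimensions.
#' @param plane `"xy"`, `"xz"` or `"yz"`.
#' @param half_angle Slab half-width in degrees (default 15).
#' @return Logical array in FFT element order.
#' @export
plane_mask <- function(shape, plane = c("xy", "xz", "yz"), half_angle = 15) {
  plane <- match.arg(plane)
  g <- freq_grid3(as.integer(shape), 1)
  normal <- switch(plane, xy = g$qz, xz = g$qy, yz = g$qx)
  out_of_plane <- asin(pmin(abs(normal) / pmax(g$q, 1e-12), 1))
  mask <- out_of_plane <= deg2rad(half_angle)
  mask[1, 1, 1] <- TRUE
  mask
}

#' Overall and plane-restricted FSC summary of a reconstruction
#'
#' Convenience wrapper computing the overall FSC average, the low/high
#' resolution-band averages (split at half Nyquist) and the averages
#' restricted to the three reciprocal planes (15-degree slabs).
#'
#' @param vol,reference Volumes on the same grid.
#' @param voxel Voxel size (A).
#' @param qmax Optional highest shell frequency (1/A) included in the
#'   averages, e.g. the imaging chain's anti-alias band limit: shells beyond
#'   it carry no transferred signal and only dilute the averages.
#' @return A one-row data.frame: `fsc_avg`, `fsc_low`, `fsc_high`,
#'   `fsc_xy`, `fsc_xz`, `fsc_yz`.
#' @export
fsc_summary <- function(vol, reference, voxel = NULL, qmax = NULL) {
  curve <- fsc(vol, reference, voxel)
  in_band <- if (is.null(qmax)) rep(TRUE, nrow(curve)) else curve$q <= qmax
  qn <- max(curve$q)
  planes <- vapply(c("xy", "xz", "yz"), function(p) {
    pc <- fsc(vol, reference, voxel, mask = plane_mask(dim(vol), p))
    fsc_average(pc, if (is.null(qmax)) "all" else pc$q <= qmax)
  }, numeric(1))
  data.frame(
    fsc_avg = fsc_average(curve, in_band),
    fsc_low = fsc_average(curve, in_band & curve$q < 0.5 * qn),
    fsc_high = fsc_average(curve, in_band & curve$q >= 0.5 * qn),
    fsc_xy = planes[["xy"]], fsc_xz = planes[["xz"]], fsc_yz = planes[["yz"]]
  )
}

#' Write an FSC curve as TSV
#'
#' @param curve An `fsc_curve`.
#' @param path Output path. Columns: q (1/A), fsc, n.
#' @return `path`, invisibly.
#' @export
write_fsc <- function(curve, path) {
  utils::write.table(curve[, c("q", "fsc", "n")], path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Soft spherical real-space mask
#'
#' A centred sphere with a raised-cosine edge, the standard masking used
#' before Fourier shell correlation in subtomogram averaging (it removes
#' solvent/noise voxels that carry no particle signal).
#'
#' @param shape Volume dimensions.
#' @param voxel Voxel size (A).
#' @param radius Mask radius (A).
#' @param soft Soft-edge width (A).
#' @return Array in [0, 1].
#' @export
spherical_mask <- function(shape, voxel, radius, soft = 6) {
  shape <- as.integer(shape)
  ax <- grid_axis(shape[1], voxel)
  ay <- grid_axis(shape[2], voxel)
  az <- grid_axis(shape[3], voxel)
  r <- sqrt(outer(outer(ax^2, ay^2, "+"), az^2, "+"))
  if (soft <= 0) return((r <= radius) * 1)
  m <- 0.5 * (1 + cos(pi * (r - radius) / soft))
  m[r <= radius] <- 1
  m[r >= radius + soft] <- 0
  m
}
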