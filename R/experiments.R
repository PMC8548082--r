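# Scaled-down in-silico studies: missing-wedge sweeps over sample geometry,
# tilt range and acquisition scheme, and projections-required analysis.
#
# Desk-scale defaults (see the methods vignette for the full reasoning):
# 64-pixel images at 2 A, a centred phantom particle of radius 40 A with a
# fixed orientation, sample thickness 120 A, total per-particle dose
# 120 e-/A^2 split equally over 35 projections, and an inelastic mean free
# path scaled so that thickness / mean-free-path matches the 150 nm / 314 nm
# lamella of the theory module. Each simulated copy stands in for an
# ensemble of identical particles (dose_scale), so the averaged map is
# signal-dominated at low tilt, the regime in which coverage and attenuation
# effects, not shot noise, set the reconstruction quality.

#' Specification of a missing-wedge sweep
#'
#' Collects the experimental factors and the desk-scale simulation settings.
#' The defaults are the package's standard study conditions; they are chosen
#' once for realism, not per run.
#'
#' @param geometries Sample shapes to sweep: subset of `c("plane",
#'   "cylinder")`.
#' @param thickness Zero-tilt slab thickness / cylinder diameter in
#'   Angstroms (vector).
#' @param max_tilts Maximum tilt angles in degrees (vector).
#' @param modes Scan modes: subset of `c("fixed_count", "fixed_increment")`.
#' @param seeds Replicate seeds (vector of small integers).
#' @param num_images Projection count in fixed_count mode.
#' @param increment Tilt increment (degrees) in fixed_increment mode;
#'   defaults to the increment that matches `num_images` over the full
#'   180-degree range, so the two modes coincide at 90 degrees.
#' @param total_dose Total electron dose per tilt series, e-/A^2, divided
#'   equally among the projections.
#' @param image_px Image size in pixels (square; also the box size).
#' @param pixel Pixel size in Angstroms.
#' @param n_atoms,particle_radius Phantom particle parameters.
#' @param n_copies Particle copies averaged per cell: each copy is imaged in
#'   its own independent ice patch and noise realisation under the same scan
#'   (equivalent to laterally separated identical particles in one lamella),
#'   and the copies are combined by wedge-masked subtomogram averaging.
#' @param ensemble Number of particles each copy stands in for (the
#'   counting-statistics multiplier `dose_scale`): with `n_copies = 2` and
#'   `ensemble = 100` the averaged map has the shot-noise statistics of a
#'   200-particle average at the stated per-particle dose, a desk-scale
#'   stand-in for the many-thousand-particle averages such studies use.
#'   Radiation damage still follows the true per-particle dose.
#' @param mfp_ratio Inelastic mean free path as a multiple of the sample
#'   thickness (default 314/150, the lamella reference ratio).
#' @param aspect Slab x-width as a multiple of its thickness (default 20/3,
#'   mirroring a 1000 nm wide, 150 nm thick lamella).
#' @param ice_variance,ice_length Gaussian-random-field ice variance (V^2)
#'   and correlation length (A).
#' @return A `sweep_spec` list.
#' @export
sweep_spec <- function(geometries = c("plane", "cylinder"),
                       thickness = 150,
                       max_tilts = c(45, 60, 75, 90),
                       modes = c("fixed_count", "fixed_increment"),
                       seeds = 1:3,
                       num_images = 35,
                       increment = NULL,
                       total_dose = 120,
                       image_px = 64,
                       pixel = 2,
                       n_atoms = 12000,
                       particle_radius = 40,
                       n_copies = 2,
                       ensemble = 100,
                       mfp_ratio = 314 / 150,
                       aspect = 20 / 3,
                       ice_variance = 1,
                       ice_length = 8) {
  stopifnot(length(geometries) > 0, length(max_tilts) > 0, total_dose > 0,
            num_images >= 2, image_px >= 16)
  structure(list(
    geometries = geometries, thickness = thickness, max_tilts = max_tilts,
    modes = modes, seeds = seeds, num_images = num_images,
    increment = increment %||% (180 / (num_images - 1)),
    total_dose = total_dose, image_px = image_px, pixel = pixel,
    n_atoms = n_atoms, particle_radius = particle_radius,
    n_copies = n_copies, ensemble = ensemble,
    mfp_ratio = mfp_ratio, aspect = aspect,
    ice_variance = ice_variance, ice_length = ice_length
  ), class = "sweep_spec")
}

# Build the per-cell configuration and sample, run the full pipeline and
# return the FSC summary. The cell is fully deterministic in (spec, seed).
run_sweep_cell <- function(spec, geometry, thickness, max_tilt, mode, seed,
                           num_images = NULL) {
  cfg <- default_config()
  cfg$detector$nx <- spec$image_px
  cfg$detector$ny <- spec$image_px
  cfg$detector$pixel_size <- spec$pixel
  cfg$simulation$pixel_size <- spec$pixel
  cfg$simulation$mean_free_path <- spec$mfp_ratio * thickness
  cfg$simulation$dose_scale <- spec$ensemble %||% 1
  cfg$scan$max_tilt <- max_tilt
  cfg$scan$mode <- mode
  cfg$scan$num_images <- num_images %||% spec$num_images
  cfg$scan$increment <- spec$increment
  cfg$scan$ordering <- "dose_symmetric"
  n_proj <- nrow(generate_scan(cfg$scan))
  cfg$beam$flux <- 1
  cfg$scan$exposure <- spec$total_dose / n_proj

  geom <- if (geometry == "plane") {
    plane_geometry(x_width = spec$aspect * thickness,
                   y_width = max(4 * spec$image_px * spec$pixel, 400),
                   z_depth = thickness)
  } else {
    cylinder_geometry(length = max(4 * spec$image_px * spec$pixel, 400),
                      radius = thickness / 2)
  }
  phantom <- make_phantom_particle(derive_seed(seed, 1), spec$n_atoms,
                                   spec$particle_radius)
  smp <- new_sample(geom)
  smp <- place_particles(smp, phantom, count = 1, orientations = "identity")

  # each particle copy sits in its own ice patch and noise realisation but
  # shares the scan, dose history and damage state
  boxes <- list()
  for (copy in seq_len(spec$n_copies)) {
    smp_c <- set_ice(smp, "grf", variance = spec$ice_variance,
                     correlation_length = spec$ice_length, voxel = 4,
                     seed = derive_seed(seed, 100 + copy))
    cfg$simulation$seed <- derive_seed(seed, 200 + copy)
    ts <- simulate_tilt_series(cfg, smp_c)
    sub <- extract_subvolumes(ts, smp_c, box = spec$image_px)
    boxes <- c(boxes, sub$boxes)
  }
  if (length(boxes) == 0) stop("all particles skipped in sweep cell")
  avg <- subtomogram_average(boxes, poses = NULL, max_tilt = max_tilt)
  truth <- render_density(phantom, rep(spec$image_px, 3), spec$pixel)
  # score under a soft spherical mask around the particle (standard practice
  # in subtomogram averaging: solvent voxels carry no particle signal)
  msk <- spherical_mask(rep(spec$image_px, 3), spec$pixel,
                        radius = spec$particle_radius + 10, soft = 6)
  # averages are reported over the band the imaging chain transfers (the
  # anti-alias aperture sits at 2/3 of the detector Nyquist frequency)
  out <- fsc_summary(array(avg * msk, dim(msk)), array(truth * msk, dim(msk)),
                     voxel = spec$pixel, qmax = (2 / 3) / (2 * spec$pixel))
  cbind(data.frame(geometry = geometry, thickness = thickness,
                   max_tilt = max_tilt, mode = mode, seed = seed,
                   n_proj = n_proj, dose_per_image = spec$total_dose / n_proj),
        out)
}

#' Run a missing-wedge sweep
#'
#' Full factorial over geometry, thickness, maximum tilt angle, scan mode
#' and seed: for each cell the pipeline builds the sample, simulates the
#' tilt series at constant total dose, phase-flips, reconstructs the
#' particle by weighted back projection, applies the wedge-masked
#' subtomogram average and scores it against the ground-truth density.
#' Deterministic for a given spec (bit-identical tables on re-run).
#'
#' @param spec A [sweep_spec()].
#' @param progress Print per-cell progress to stderr.
#' @return A data.frame with one row per cell: factors, `n_proj`,
#'   `dose_per_image`, overall/low/high FSC averages and the three
#'   reciprocal-plane FSC averages.
#' @export
run_missing_wedge_sweep <- function(spec, progress = FALSE) {
  cells <- expand.grid(geometry = spec$geometries, thickness = spec$thickness,
                       max_tilt = spec$max_tilts, mode = spec$modes,
                       seed = spec$seeds, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    c_i <- cells[i, ]
    if (progress) {
      message(sprintf("[%d/%d] %s D=%g tilt=%g %s seed=%d", i, nrow(cells),
                      c_i$geometry, c_i$thickness, c_i$max_tilt, c_i$mode,
                      c_i$seed))
    }
    rows[[i]] <- run_sweep_cell(spec, c_i$geometry, c_i$thickness,
                                c_i$max_tilt, c_i$mode, c_i$seed)
  }
  do.call(rbind, rows)
}

#' Reconstruction quality as a function of projection count
#'
#' Runs the sweep cell at a fixed geometry and tilt range for each
#' projection count (fixed-count mode, constant total dose).
#'
#' @param spec A [sweep_spec()].
#' @param geometry `"plane"` or `"cylinder"`.
#' @param max_tilt Maximum tilt (degrees).
#' @param n_list Projection counts to evaluate.
#' @param seed Replicate seed.
#' @return Data.frame of cells with FSC summaries, ordered by `n_proj`.
#' @export
quality_vs_projections <- function(spec, geometry, max_tilt, n_list,
                                   seed = 1) {
  rows <- lapply(sort(n_list), function(n) {
    run_sweep_cell(spec, geometry, spec$thickness[1], max_tilt,
                   "fixed_count", seed, num_images = n)
  })
  do.call(rbind, rows)
}

#' Projections required to match a reference reconstruction quality
#'
#' Compares two quality-vs-projections curves: for each target quality
#' level, finds the minimal projection count reaching that level on each
#' curve (monotone linear interpolation on the plateau-clipped, i.e. running
#' maximum, curve) and reports the ratio `n_ref / n_other`. Levels default
#' to the 25/50/75% points of the `other` curve's dynamic range; levels
#' unreachable by either curve are recorded as NA.
#'
#' @param ref Curve for the reference condition (e.g. no-wedge cylinder),
#'   from [quality_vs_projections()].
#' @param other Curve for the comparison condition (e.g. 120-degree-range
#'   planar sample).
#' @param levels Target quality levels; NULL for the default mid-range
#'   levels.
#' @param metric Column to match on (default `"fsc_avg"`; any FSC column).
#' @return Data.frame with `level`, `n_ref`, `n_other`, `fraction`.
#' @export
projections_required <- function(ref, other, levels = NULL,
                                 metric = "fsc_avg") {
  n_at_level <- function(curve, lev) {
    o <- order(curve$n_proj)
    n <- curve$n_proj[o]
    qual <- cummax(curve[[metric]][o]) # plateau-clipped monotone curve
    if (lev > max(qual)) return(NA_real_)
    if (lev <= qual[1]) return(n[1])
    # minimal n attaining the level: interpolate within the first segment
    # that crosses it (the clipped curve may have plateaus/ties)
    i <- which(qual >= lev)[1]
    n[i - 1] + (n[i] - n[i - 1]) * (lev - qual[i - 1]) / (qual[i] - qual[i - 1])
  }
  if (is.null(levels)) {
    o <- order(other$n_proj)
    qual <- cummax(other[[metric]][o])
    levels <- min(qual) + c(0.25, 0.5, 0.75) * (max(qual) - min(qual))
  }
  res <- data.frame(
    level = levels,
    n_ref = vapply(levels, function(l) n_at_level(ref, l), numeric(1)),
    n_other = vapply(levels, function(l) n_at_level(other, l), numeric(1))
  )
  res$fraction <- res$n_ref / res$n_other
  res
}

#' Locate the tilt angle where a quality curve peaks or plateaus
#'
#' For a sweep result restricted to one condition, computes the per-tilt
#' median of the chosen metric over seeds and returns the tilt with the
#' maximum median (the smallest such tilt if the maximum is attained more
#' than once, i.e. the onset of the plateau).
#'
#' @param sweep A [run_missing_wedge_sweep()] result (already filtered to
#'   one geometry/mode/thickness).
#' @param metric Quality column (default `"fsc_avg"`).
#' @return List with `tilt` (degrees), and the `medians` table.
#' @export
peak_tilt <- function(sweep, metric = "fsc_avg") {
  med <- stats::aggregate(sweep[[metric]],
                          by = list(max_tilt = sweep$max_tilt), FUN = median)
  names(med)[2] <- metric
  best <- med$max_tilt[which.max(med[[metric]])]
  list(tilt = min(best), medians = med)
}
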