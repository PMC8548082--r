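# Tilt-series simulation: the full imaging chain per acquisition-plan entry,
# with dose bookkeeping for the beam-damage model.

#' Simulate a tilt series
#'
#' Expands the scan model into an acquisition plan ([generate_scan()]) and,
#' for each projection in acquisition order: accumulates dose, applies the
#' beam-damage filter at the accumulated dose, projects the potential at the
#' tilt angle, runs the multislice propagation, applies the optics (CTF) and
#' the detector model. The accumulated dose of the k-th acquired image is
#' `k * flux * exposure`, so a dose-symmetric ordering exposes low tilts to
#' the least damage. Beam drift and stage translation offsets are applied to
#' the sample position before each exposure (documented convention).
#'
#' `simulation$dose_scale` multiplies the dose seen by the detector's
#' counting statistics only: a value M emulates averaging M identical
#' particles in independent shot-noise realisations (the Poisson statistics
#' of the scaled exposure equal those of the M-particle average), while
#' radiation damage continues to follow the true per-particle accumulated
#' dose. Used by the scaled-down ensemble studies.
#'
#' @param config A `twin_config` (see [default_config()]); the image grid is
#'   the detector grid.
#' @param sample A `twin_sample`.
#' @return A `tilt_series`: `images` array (nx x ny x N electron counts, in
#'   acquisition order), `meta` data.frame (`index`, `angle`, `exposure`,
#'   `cumulative_exposure`, `dose_per_image`, `accumulated_dose`, `defocus`,
#'   `pixel`), `pixel` (A) and the `config` used.
#' @export
simulate_tilt_series <- function(config, sample) {
  stopifnot(inherits(sample, "twin_sample"))
  plan <- generate_scan(config$scan)
  n <- nrow(plan)
  det <- config$detector
  sim <- config$simulation
  grid <- grid_spec(det$nx, det$ny, det$pixel_size, sim$slice_thickness)
  dose_per_image <- config$beam$flux * config$scan$exposure
  ctf <- ctf_evaluate(config$lens, config$beam, det$nx, det$ny,
                      det$pixel_size)

  # materialise the GRF ice field once so all tilts see the same specimen
  if (identical(sample$ice$model, "grf") && is.null(sample$ice$field)) {
    half <- geometry_half_extent(sample$geometry)
    shape <- pmax(8L, as.integer(ceiling(2 * half / sample$ice$voxel)) + 4L)
    sample$ice$field <- ice_grf(shape, sample$ice$voxel, sample$ice$mean,
                                sample$ice$variance,
                                sample$ice$correlation_length,
                                sample$ice$seed)
  }

  # beam drift / stage translation offsets per acquired image
  drift <- config$beam$drift
  offsets <- matrix(0, n, 2)
  if (identical(drift$model, "random") && drift$amplitude > 0) {
    offsets <- with_seed(drift$seed %||% 0,
                         matrix(stats::rnorm(2 * n, sd = drift$amplitude), n, 2))
  } else if (identical(drift$model, "sinusoidal") && drift$amplitude > 0) {
    offsets[, 1] <- drift$amplitude * sin(2 * pi * plan$index / (drift$period %||% 10))
  }
  offsets[, 1] <- offsets[, 1] + (config$scan$translation %||% 0) * (plan$index - 1)

  images <- array(0, c(det$nx, det$ny, n))
  clipped <- 0L
  with_seed(sim$seed %||% 0, {
    for (k in seq_len(n)) {
      acc_dose <- k * dose_per_image
      b <- damage_b_factor(acc_dose, sim$damage_sensitivity)
      pot <- project_potential(sample, plan$angle[k], grid, damage_b = b,
                               offset = offsets[k, ],
                               atom_amplitude = sim$atom_amplitude %||% 30,
                               atom_sigma = sim$atom_sigma %||% 1.0)
      wave <- multislice(pot, config$beam,
                         mean_free_path = sim$mean_free_path %||% Inf,
                         band_limit = isTRUE(sim$band_limit))
      img <- apply_optics(wave, ctf)
      counts <- apply_detector(img, det,
                               dose_per_image * (sim$dose_scale %||% 1))
      clipped <- clipped + attr(counts, "clipped")
      images[, , k] <- counts
    }
  })

  meta <- data.frame(
    index = plan$index,
    angle = plan$angle,
    exposure = plan$exposure,
    cumulative_exposure = plan$cumulative_exposure,
    dose_per_image = dose_per_image,
    accumulated_dose = plan$index * dose_per_image,
    defocus = config$lens$defocus,
    pixel = det$pixel_size
  )
  structure(
    list(images = images, meta = meta, pixel = det$pixel_size,
         config = config, clipped = clipped),
    class = "tilt_series"
  )
}

#' Convert detector counts to zero-mean fractional contrast
#'
#' Phase-contrast reconstruction works on `(counts - mean) / mean` per
#' image, which removes the dose and attenuation scale while preserving the
#' relative contrast the CTF transfers.
#'
#' @param ts A `tilt_series`, or a plain image stack array.
#' @return Array of the same shape.
#' @export
tilt_contrast <- function(ts) {
  images <- if (inherits(ts, "tilt_series")) ts$images else ts
  out <- images
  for (k in seq_len(dim(images)[3])) {
    m <- mean(images[, , k])
    out[, , k] <- if (m > 0) (images[, , k] - m) / m else 0
  }
  out
}
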