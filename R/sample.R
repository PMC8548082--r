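# Virtual specimen assembly: particle placement with non-overlap and
# containment guarantees, milling, amorphous-ice models, persistence.

SAMPLE_SCHEMA <- "cryotwin-sample-v1"

#' Create an empty sample
#'
#' @param geometry A `twin_geometry` from [plane_geometry()] or
#'   [cylinder_geometry()].
#' @return A `twin_sample` with no particles and no ice.
#' @export
new_sample <- function(geometry) {
  stopifnot(inherits(geometry, "twin_geometry"))
  structure(
    list(
      geometry = geometry,
      models = list(),
      particles = data.frame(
        model_id = character(), x = numeric(), y = numeric(), z = numeric(),
        qw = numeric(), qx = numeric(), qy = numeric(), qz = numeric(),
        bounding_radius = numeric(), stringsAsFactors = FALSE
      ),
      ice = list(model = "none"),
      milled_regions = character()
    ),
    class = "twin_sample"
  )
}

# Centre a model on its centroid; returns list(model, bounding_radius)
centre_model <- function(model) {
  ctr <- c(mean(model$x), mean(model$y), mean(model$z))
  model$x <- model$x - ctr[1]
  model$y <- model$y - ctr[2]
  model$z <- model$z - ctr[3]
  list(model = model, bounding_radius = sqrt(max(model$x^2 + model$y^2 + model$z^2)))
}

#' Place particle instances into a sample
#'
#' Adds `count` instances of an atomic model. Positions default to the
#' geometry centre for a single particle (the conventional central pose) and
#' to rejection-sampled random positions otherwise; orientations default to
#' uniform random rotations (quaternion method). Placement guarantees that
#' bounding spheres of distinct particles do not overlap and that every
#' particle, by its bounding radius, lies strictly inside the geometry.
#' Rejection sampling tries at most `max_attempts` positions per particle
#' and then fails reporting the achieved count.
#'
#' @param sample A `twin_sample`.
#' @param model An `atomic_model` (it is re-centred on its centroid; the
#'   instance position is the particle centroid).
#' @param count Number of instances (ignored when `positions` is given).
#' @param positions Optional n x 3 matrix of explicit centres (Angstroms).
#' @param orientations Optional n x 4 matrix of unit quaternions (w, x, y,
#'   z), or the string `"identity"`. A single row is recycled to all
#'   instances (the common fixed-orientation layout used when probing
#'   direction-dependent artefacts).
#' @param model_id Name under which the model is stored.
#' @param seed Optional seed for reproducible placement.
#' @param max_attempts Rejection-sampling bound per particle.
#' @return The updated `twin_sample`.
#' @export
place_particles <- function(sample, model, count = 1, positions = NULL,
                            orientations = NULL, model_id = "particle",
                            seed = NULL, max_attempts = 10000) {
  stopifnot(inherits(sample, "twin_sample"))
  cm <- centre_model(model)
  rb <- cm$bounding_radius
  geom <- sample$geometry
  run <- function() {
    n <- if (!is.null(positions)) nrow(matrix(positions, ncol = 3)) else count
    if (n == 0) return(sample)
    # orientations
    q <- if (is.null(orientations)) {
      quat_random(n)
    } else if (identical(orientations, "identity")) {
      matrix(rep(quat_identity(), n), ncol = 4, byrow = TRUE)
    } else {
      m <- matrix(orientations, ncol = 4)
      m <- m[rep(seq_len(nrow(m)), length.out = n), , drop = FALSE]
      m / sqrt(rowSums(m^2))
    }
    existing <- as.matrix(sample$particles[, c("x", "y", "z")])
    existing_rb <- sample$particles$bounding_radius
    if (!is.null(positions)) {
      pos <- matrix(positions, ncol = 3)
      ok <- geometry_contains(geom, pos, margin = rb)
      if (!all(ok)) stop("explicit particle position(s) outside geometry (with bounding-radius margin)")
      pos_list <- pos
    } else if (count == 1 && nrow(existing) == 0) {
      # single particle: centre of the sample volume
      pos_list <- matrix(0, 1, 3)
      if (!geometry_contains(geom, pos_list, margin = rb)) {
        stop("placed 0 of 1 particles: bounding radius ", signif(rb, 4),
             " A does not fit the geometry")
      }
    } else {
      half <- geometry_half_extent(geom)
      pos_list <- matrix(NA_real_, n, 3)
      for (i in seq_len(n)) {
        placed <- FALSE
        for (attempt in seq_len(max_attempts)) {
          p <- (stats::runif(3) * 2 - 1) * half
          if (!geometry_contains(geom, matrix(p, 1), margin = rb)) next
          all_pos <- rbind(existing, pos_list[seq_len(i - 1), , drop = FALSE])
          all_rb <- c(existing_rb, rep(rb, i - 1))
          if (nrow(all_pos) > 0) {
            d2 <- rowSums(sweep(all_pos, 2, p)^2)
            if (any(d2 < (all_rb + rb)^2)) next
          }
          pos_list[i, ] <- p
          placed <- TRUE
          break
        }
        if (!placed) {
          stop("placed ", i - 1, " of ", n, " particles within ",
               max_attempts, " attempts each; geometry too crowded")
        }
      }
    }
    # overlap check for explicit positions too
    all_pos <- rbind(existing, pos_list)
    all_rb <- c(existing_rb, rep(rb, nrow(pos_list)))
    if (nrow(all_pos) > 1) {
      d <- as.matrix(stats::dist(all_pos))
      lim <- outer(all_rb, all_rb, "+")
      diag(d) <- Inf
      if (any(d < lim)) stop("particle bounding spheres overlap")
    }
    sample$models[[model_id]] <- cm$model
    sample$particles <- rbind(
      sample$particles,
      data.frame(model_id = model_id, x = pos_list[, 1], y = pos_list[, 2],
                 z = pos_list[, 3], qw = q[, 1], qx = q[, 2], qy = q[, 3],
                 qz = q[, 4], bounding_radius = rb, stringsAsFactors = FALSE)
    )
    sample
  }
  if (!is.null(seed)) with_seed(seed, run()) else run()
}

#' World-frame atom table of a sample
#'
#' Applies each instance's orientation and position to its model and stacks
#' the results, optionally including atomistic (random-water) ice.
#'
#' @param sample A `twin_sample`.
#' @param include_ice Include random-water ice atoms when present.
#' @return A data.frame with `element`, `x`, `y`, `z`, `occupancy`.
#' @export
sample_atoms <- function(sample, include_ice = TRUE) {
  parts <- lapply(seq_len(nrow(sample$particles)), function(i) {
    inst <- sample$particles[i, ]
    model <- sample$models[[inst$model_id]]
    rot <- quat_to_matrix(c(inst$qw, inst$qx, inst$qy, inst$qz))
    xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(rot)
    data.frame(element = model$element,
               x = xyz[, 1] + inst$x, y = xyz[, 2] + inst$y,
               z = xyz[, 3] + inst$z, occupancy = model$occupancy,
               stringsAsFactors = FALSE)
  })
  if (include_ice && identical(sample$ice$model, "random_water")) {
    parts <- c(parts, list(as.data.frame(sample$ice$atoms)))
  }
  if (length(parts) == 0) {
    return(data.frame(element = character(), x = numeric(), y = numeric(),
                      z = numeric(), occupancy = numeric()))
  }
  do.call(rbind, parts)
}

#' Mill a sample to an arbitrary shape
#'
#' Removes all atoms for which the region predicate is FALSE (evaluated in
#' world coordinates). Particle instances left without atoms are dropped.
#' The milled region is recorded in the sample metadata.
#'
#' @param sample A `twin_sample`.
#' @param region A vectorised predicate `function(x, y, z)` returning TRUE
#'   for points to keep.
#' @param label Optional description stored in the sample metadata.
#' @return The milled `twin_sample`.
#' @export
mill <- function(sample, region, label = "milled region") {
  keep_rows <- logical(nrow(sample$particles))
  for (i in seq_len(nrow(sample$particles))) {
    inst <- sample$particles[i, ]
    model <- sample$models[[inst$model_id]]
    rot <- quat_to_matrix(c(inst$qw, inst$qx, inst$qy, inst$qz))
    xyz <- as.matrix(model[, c("x", "y", "z")]) %*% t(rot)
    wx <- xyz[, 1] + inst$x; wy <- xyz[, 2] + inst$y; wz <- xyz[, 3] + inst$z
    keep <- region(wx, wy, wz)
    keep_rows[i] <- any(keep)
    if (any(keep) && !all(keep)) {
      # instance gets its own milled model, stored in world-local coords
      new_id <- sprintf("%s#milled%d", inst$model_id, i)
      kept <- new_atomic_model(model$element[keep], wx[keep] - inst$x,
                               wy[keep] - inst$y, wz[keep] - inst$z,
                               model$occupancy[keep])
      sample$models[[new_id]] <- kept
      sample$particles$model_id[i] <- new_id
      # orientation is folded into the stored coordinates
      sample$particles[i, c("qw", "qx", "qy", "qz")] <- c(1, 0, 0, 0)
      sample$particles$bounding_radius[i] <-
        sqrt(max(kept$x^2 + kept$y^2 + kept$z^2))
    }
  }
  sample$particles <- sample$particles[keep_rows, , drop = FALSE]
  used <- unique(sample$particles$model_id)
  sample$models <- sample$models[names(sample$models) %in% used]
  if (identical(sample$ice$model, "random_water")) {
    a <- sample$ice$atoms
    keep <- region(a$x, a$y, a$z)
    sample$ice$atoms <- a[keep, , drop = FALSE]
  }
  sample$milled_regions <- c(sample$milled_regions, label)
  sample
}

#' Random-water amorphous ice
#'
#' Fills the geometry with rigid water molecules (O-H 0.9572 A, H-O-H
#' 104.52 degrees) at uniform random positions and orientations. The number
#' of molecules is `round(density * volume)`. No minimum intermolecular
#' distance is enforced, so molecules may sit at unphysically short
#' distances; relaxing them would require molecular dynamics, which is out
#' of scope.
#'
#' @param geometry A `twin_geometry`.
#' @param density Molecules per cubic Angstrom (> 0; 0 gives an empty
#'   model). Vitreous ice at 0.94 g/cm^3 corresponds to about 0.031
#'   molecules/A^3, the package's documented reference value.
#' @param seed Integer seed.
#' @return An `atomic_model` of O, H, H atoms per molecule (world frame).
#' @export
ice_random_water <- function(geometry, density, seed = 0) {
  stopifnot(density >= 0)
  n <- round(density * geometry_volume(geometry))
  if (n == 0) return(new_atomic_model(character(), numeric(), numeric(), numeric()))
  with_seed(seed, {
    half <- geometry_half_extent(geometry)
    centres <- matrix(NA_real_, 0, 3)
    # keep molecule centres 1 A from the surface so the H atoms stay inside
    while (nrow(centres) < n) {
      m <- max(2 * (n - nrow(centres)), 1000)
      cand <- cbind(stats::runif(m, -half[1], half[1]),
                    stats::runif(m, -half[2], half[2]),
                    stats::runif(m, -half[3], half[3]))
      cand <- cand[geometry_contains(geometry, cand, margin = 1), , drop = FALSE]
      centres <- rbind(centres, cand)
    }
    centres <- centres[seq_len(n), , drop = FALSE]
    # rigid water geometry in the molecular frame
    doh <- 0.9572
    ang <- deg2rad(104.52)
    h1 <- c(doh, 0, 0)
    h2 <- c(doh * cos(ang), doh * sin(ang), 0)
    q <- quat_random(n)
    h1w <- t(vapply(seq_len(n), function(i) quat_to_matrix(q[i, ]) %*% h1,
                    numeric(3)))
    h2w <- t(vapply(seq_len(n), function(i) quat_to_matrix(q[i, ]) %*% h2,
                    numeric(3)))
    new_atomic_model(
      rep(c("O", "H", "H"), n),
      as.vector(rbind(centres[, 1], centres[, 1] + h1w[, 1], centres[, 1] + h2w[, 1])),
      as.vector(rbind(centres[, 2], centres[, 2] + h1w[, 2], centres[, 2] + h2w[, 2])),
      as.vector(rbind(centres[, 3], centres[, 3] + h1w[, 3], centres[, 3] + h2w[, 3]))
    )
  })
}

#' Gaussian-random-field amorphous ice
#'
#' Synthesises a stationary Gaussian random field as Fourier-filtered white
#' noise with a Gaussian-correlation power spectrum
#' \eqn{P(q) \propto \exp(-q^2 \ell^2 / 2)}, scaled so the expected voxel
#' variance equals `variance`, plus the constant `mean`. The spectrum family
#' is a documented stand-in for a physically calibrated ice spectrum and is
#' pluggable through the `spectrum` argument.
#'
#' @param shape Integer vector of grid dimensions, e.g. `c(64, 64, 64)`.
#' @param voxel Voxel size in Angstroms.
#' @param mean Field mean (Volts, potential units).
#' @param variance Field variance (Volts^2); 0 gives the constant field.
#' @param correlation_length Correlation length in Angstroms (> 0).
#' @param seed Integer seed.
#' @param mask Optional logical/numeric array of `shape` confining the field
#'   to the sample interior (field is zero outside the mask).
#' @param spectrum Optional function of `q` (1/Angstrom) returning the
#'   amplitude filter; overrides the Gaussian-correlation default.
#' @return A numeric array of `shape` with attributes `voxel` and `params`.
#' @export
ice_grf <- function(shape, voxel, mean = 0, variance = 1,
                    correlation_length = 8, seed = 0, mask = NULL,
                    spectrum = NULL) {
  stopifnot(variance >= 0, correlation_length > 0, voxel > 0)
  shape <- as.integer(shape)
  field <- if (variance == 0) {
    array(mean, shape)
  } else {
    with_seed(seed, {
      w <- array(stats::rnorm(prod(shape)), shape)
      g <- freq_grid3(shape, voxel)
      h <- if (is.null(spectrum)) {
        exp(-g$q^2 * correlation_length^2 / 4) # amplitude = sqrt(power)
      } else {
        spectrum(g$q)
      }
      f <- fourier_filter(w, h)
      # unit-variance white noise through filter h has voxel variance
      # mean(h^2); rescale to the requested variance
      f <- f * sqrt(variance / base::mean(h^2))
      f + mean
    })
  }
  if (!is.null(mask)) field <- field * (mask != 0)
  attr(field, "voxel") <- voxel
  attr(field, "params") <- list(mean = mean, variance = variance,
                                correlation_length = correlation_length,
                                seed = seed)
  class(field) <- c("grf_field", class(field))
  field
}

#' Attach an ice model to a sample
#'
#' @param sample A `twin_sample`.
#' @param model One of `"none"`, `"random_water"` or `"grf"`.
#' @param ... Model parameters: `density` and `seed` for random water;
#'   `mean`, `variance` (Volts), `correlation_length` (A), `voxel` (A) and
#'   `seed` for the Gaussian random field (the field itself is generated
#'   lazily at projection time over the needed grid, or eagerly here when
#'   `shape` is supplied).
#' @return The updated `twin_sample`.
#' @export
set_ice <- function(sample, model = c("none", "random_water", "grf"), ...) {
  model <- match.arg(model)
  args <- list(...)
  if (model == "none") {
    sample$ice <- list(model = "none")
  } else if (model == "random_water") {
    density <- args$density %||% 0.031
    sample$ice <- list(model = "random_water", density = density,
                       seed = args$seed %||% 0,
                       atoms = ice_random_water(sample$geometry, density,
                                                args$seed %||% 0))
  } else {
    sample$ice <- list(model = "grf",
                       mean = args$mean %||% 0,
                       variance = args$variance %||% 1,
                       correlation_length = args$correlation_length %||% 8,
                       voxel = args$voxel %||% 4,
                       seed = args$seed %||% 0,
                       field = NULL)
    if (!is.null(args$shape)) {
      sample$ice$field <- ice_grf(args$shape, sample$ice$voxel,
                                  sample$ice$mean, sample$ice$variance,
                                  sample$ice$correlation_length,
                                  sample$ice$seed)
    }
  }
  sample
}

#' Persist a sample to disk
#'
#' Writes the full sample (geometry, models, particle poses, ice parameters)
#' to a schema-versioned archive; [sample_load()] restores it losslessly
#' (atom coordinates round-trip bit-exactly).
#'
#' @param sample A `twin_sample`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
sample_store <- function(sample, path) {
  stopifnot(inherits(sample, "twin_sample"))
  saveRDS(list(schema = SAMPLE_SCHEMA, sample = sample), path)
  invisible(path)
}

#' Load a sample stored by [sample_store()]
#'
#' @param path Archive path.
#' @return The `twin_sample`.
#' @export
sample_load <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$schema, SAMPLE_SCHEMA)) {
    stop("sample archive schema mismatch: found '",
         paste(obj$schema, collapse = ""), "', expected '", SAMPLE_SCHEMA, "'")
  }
  obj$sample
}
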