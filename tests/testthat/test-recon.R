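test_that("phase flipping is idempotent squared and inert for positive CTF", {
  set.seed(1)
  img <- matrix(rnorm(64 * 64), 64, 64)
  ctf <- ctf_evaluate(table1_lens(), table1_beam(), 64, 64, 2)
  flipped <- phase_flip(img, ctf)
  expect_equal(phase_flip(flipped, ctf), img, tolerance = 1e-10)
  # an all-positive transfer changes nothing
  lens <- table1_lens(); lens$defocus <- 0; lens$spherical_aberration <- 0
  lens$phase_plate_shift <- pi / 2
  ctf_pos <- ctf_evaluate(lens, table1_beam(), 64, 64, 2)
  expect_true(all(ctf_pos$imag > 0))
  expect_equal(phase_flip(img, ctf_pos), img, tolerance = 1e-10)
  expect_error(phase_flip(matrix(0, 8, 8), ctf), "grid")
})

test_that("phase flipping raises correlation with the true projection", {
  # weak-phase particle imaged with the standard optics; the CTF-corrupted
  # contrast anti-correlates with truth beyond the first zero, flipping fixes it
  phantom <- make_phantom_particle(2, 400, 18)
  geom <- plane_geometry(600, 400, 44)
  s <- place_particles(new_sample(geom), phantom, count = 1,
                       orientations = "identity")
  grid <- grid_spec(64, 64, 2, 5)
  pot <- project_potential(s, 0, grid)
  w <- multislice(pot, table1_beam())
  ctf <- ctf_evaluate(table1_lens(), table1_beam(), 64, 64, 2)
  img <- apply_optics(w, ctf)
  contrast <- img - mean(img)
  vproj <- apply(pot$slices, c(1, 2), sum)
  truth <- vproj - mean(vproj)
  r0 <- stats::cor(as.vector(contrast), as.vector(truth))
  r1 <- stats::cor(as.vector(phase_flip(contrast, ctf)), as.vector(truth))
  expect_gt(r1, r0)
  expect_gt(r1, 0.5)
})

test_that("WBP gap weights reduce to the classical ramp for equal spacing", {
  w <- cryotwin:::angular_gap_weights(seq(-88, 90, by = 2))
  expect_equal(w, rep(pi / 90, 90), tolerance = 1e-12)
  # irregular angles: weights proportional to local gaps
  w2 <- cryotwin:::angular_gap_weights(c(0, 10, 40))
  expect_equal(w2, cryotwin:::deg2rad(c(10, 20, 30)), tolerance = 1e-12)
})

test_that("WBP localises a point phantom to within one voxel", {
  n <- 32
  angles <- seq(-90, 88, by = 2)
  true_pos <- c(5, -3, 7) # voxel offsets from centre, A with 1 A voxels
  projections <- array(0, c(n, n, length(angles)))
  for (k in seq_along(angles)) {
    a <- cryotwin:::deg2rad(angles[k])
    xp <- true_pos[1] * cos(a) + true_pos[3] * sin(a)
    ix <- round(xp) + n / 2 + 1
    iy <- round(true_pos[2]) + n / 2 + 1
    projections[ix, iy, k] <- 1
  }
  vol <- wbp_reconstruct(projections, angles, c(n, n, n), pixel = 1)
  peak <- which(vol == max(vol), arr.ind = TRUE)[1, ]
  expect_true(all(abs(peak - (true_pos + n / 2 + 1)) <= 1))
  expect_error(wbp_reconstruct(projections[, , 1, drop = FALSE], angles[1],
                               c(n, n, n), 1), ">= 2")
})

test_that("WBP matches a dense least-squares solution on a 2D toy system", {
  # 2-angle toy: reconstruct a 8x1x8 grid from projections at 0 and 90 deg;
  # compare against the minimum-norm least-squares solution of the explicit
  # projection operator (same geometry, same bilinear footprint)
  n <- 8
  angles <- c(0, 90)
  set.seed(3)
  truth <- array(0, c(n, 1, n))
  truth[3, 1, 5] <- 1; truth[6, 1, 2] <- 0.5
  # explicit projection matrix rows: one per (angle, detector pixel)
  a_rows <- list(); p_vec <- c()
  for (a in angles) {
    op <- cryotwin:::bp_operators(a, c(n, 1, n), 1, n, 1, 1)
    a_mat <- as.matrix(Matrix::t(op$wxz)) # nxp x (n*n): projection operator
    a_rows[[length(a_rows) + 1]] <- a_mat
    p_vec <- c(p_vec, as.vector(a_mat %*% as.vector(truth[, 1, ])))
  }
  amat <- do.call(rbind, a_rows)
  ls <- MASS::ginv(amat) %*% p_vec
  projections <- array(p_vec, c(n, 1, 2))
  wbp <- wbp_reconstruct(projections, angles, c(n, 1, n), pixel = 1)
  r <- stats::cor(as.vector(wbp[, 1, ]), as.vector(ls))
  expect_gt(r, 0.85)
})

test_that("wedge masks cover the sampled double cone", {
  m90 <- wedge_mask(90, c(32, 32, 32))
  expect_true(all(m90 == 1))
  m60 <- wedge_mask(60, c(32, 32, 32))
  # fraction of in-plane directions sampled, on a disc to equalise angular
  # density: 2 * 60 / 180
  g <- cryotwin:::freq_grid3(c(32, 32, 32), 1)
  disc <- sqrt(g$qx^2 + g$qz^2) <= 0.5 & sqrt(g$qx^2 + g$qz^2) > 0.05
  expect_equal(mean(m60[disc]), 120 / 180, tolerance = 0.03)
  # invariant along the rotation axis (y)
  expect_equal(m60[5, 1, 9], m60[5, 17, 9])
  expect_equal(m60[2, 8, 30], m60[2, 25, 30])
})

test_that("volume rotation matches the quaternion applied to the model", {
  phantom <- make_phantom_particle(4, 600, 18)
  q <- cryotwin:::quat_normalize(c(0.9, 0.1, 0.3, -0.2))
  rot <- cryotwin:::quat_to_matrix(q)
  rotated_model <- phantom
  xyz <- as.matrix(phantom[, c("x", "y", "z")]) %*% t(rot)
  rotated_model$x <- xyz[, 1]; rotated_model$y <- xyz[, 2]; rotated_model$z <- xyz[, 3]
  # render with a width comfortably above the voxel size so trilinear
  # resampling fidelity, not aliasing, is what the check measures
  vol_ref <- render_density(phantom, c(48, 48, 48), 1.5, atom_sigma = 2.5)
  vol_rot <- render_density(rotated_model, c(48, 48, 48), 1.5, atom_sigma = 2.5)
  back <- rotate_volume(vol_rot, q)
  msk <- spherical_mask(c(48, 48, 48), 1.5, 22, 4)
  r <- stats::cor(as.vector(back * msk), as.vector(vol_ref * msk))
  expect_gt(r, 0.97)
})

test_that("subtomogram averaging obeys its mask algebra and raises FSC", {
  dmv <- c(24, 24, 24)
  truth <- render_density(make_phantom_particle(5, 300, 12), dmv, 1.5)
  # identical boxes with full masks average to the box itself
  avg_same <- subtomogram_average(list(truth, truth), max_tilt = 90)
  expect_equal(as.numeric(avg_same), as.numeric(truth), tolerance = 1e-10)
  # Monte-Carlo averaging gain: 24 noisy copies beat a single copy
  set.seed(8)
  noisy <- lapply(1:24, function(i) {
    truth + array(rnorm(prod(dmv), sd = 8 * stats::sd(as.numeric(truth))), dmv)
  })
  avg <- subtomogram_average(noisy, max_tilt = 90)
  f_one <- fsc(noisy[[1]], truth, voxel = 1.5)
  f_avg <- fsc(avg, truth, voxel = 1.5)
  sel <- !is.na(f_one$fsc) & f_one$shell > 1
  expect_true(all(f_avg$fsc[sel] > f_one$fsc[sel]))
})

test_that("complementary wedges unite their Fourier coverage", {
  dmv <- c(16, 16, 16)
  m1 <- wedge_mask(45, dmv)
  # a second particle rotated 90 degrees about y samples the complement
  q90 <- c(cos(pi / 4), 0, sin(pi / 4), 0)
  m2 <- cryotwin:::rotated_wedge_mask(45, dmv, q90)
  expect_gt(mean((m1 + m2) > 0), 0.99)
})

test_that("FSC self-tests: identity, sign flip, and white-noise null", {
  vol <- render_density(make_phantom_particle(6, 400, 14), c(32, 32, 32), 1)
  f_self <- fsc(vol, vol)
  ok <- !is.na(f_self$fsc)
  expect_true(all(abs(f_self$fsc[ok] - 1) < 1e-9))
  f_anti <- fsc(vol, -vol)
  expect_true(all(abs(f_anti$fsc[ok] + 1) < 1e-9))
  set.seed(10)
  a <- array(rnorm(64^3), c(64, 64, 64))
  b <- array(rnorm(64^3), c(64, 64, 64))
  f_null <- fsc(a, b)
  frac <- mean(abs(f_null$fsc) <= 3 / sqrt(f_null$n), na.rm = TRUE)
  expect_gte(frac, 0.95)
})

test_that("FSC average implements the element-weighted formula", {
  curve <- structure(
    data.frame(shell = 1:2, q = c(0.1, 0.2), fsc = c(1, 0), n = c(1, 3)),
    class = c("fsc_curve", "data.frame")
  )
  expect_equal(fsc_average(curve), 0.25)
  curve1 <- curve; curve1$fsc <- c(1, 1)
  expect_equal(fsc_average(curve1), 1)
  expect_error(fsc_average(curve, function(q) q > 1), "empty")
})

test_that("plane-restricted FSC of an isotropic pair matches the full average", {
  set.seed(11)
  vol <- render_density(make_phantom_particle(12, 500, 14), c(32, 32, 32), 1)
  noisy <- vol + array(rnorm(32^3, sd = 2 * stats::sd(as.numeric(vol))),
                       c(32, 32, 32))
  full <- fsc_average(fsc(noisy, vol))
  planes <- vapply(c("xy", "xz", "yz"), function(p) {
    fsc_average(fsc(noisy, vol, mask = plane_mask(c(32, 32, 32), p)))
  }, numeric(1))
  expect_true(all(abs(planes - full) < 0.15))
})

test_that("subvolume extraction centres boxes and skips edge particles", {
  cfg <- default_config()
  cfg$detector$nx <- 48; cfg$detector$ny <- 48; cfg$detector$pixel_size <- 2
  cfg$simulation$pixel_size <- 2
  # full rotation and moderate underfocus so the box shows a compact,
  # ring-free particle whose peak position is meaningful
  cfg$scan$max_tilt <- 90; cfg$scan$mode <- "fixed_count"
  cfg$scan$num_images <- 13
  cfg$lens$defocus <- 5000
  cfg$beam$flux <- 100; cfg$scan$exposure <- 1
  cfg$simulation$dose_scale <- 100
  geom <- plane_geometry(90, 90, 50)
  phantom <- make_phantom_particle(9, 300, 12)
  s <- place_particles(new_sample(geom), phantom, count = 1,
                       orientations = "identity")
  ts <- simulate_tilt_series(cfg, s)
  sub <- extract_subvolumes(ts, s, box = 24)
  expect_equal(length(sub$boxes), 1)
  expect_equal(sub$skipped, 0)
  # the box's density maximum falls where the ground truth's maximum is
  # (a random phantom's densest spot need not be its centroid)
  msk <- spherical_mask(c(24, 24, 24), 2, 14, 4)
  truth <- render_density(phantom, c(24, 24, 24), 2)
  peak <- which(sub$boxes[[1]] * msk == max(sub$boxes[[1]] * msk), arr.ind = TRUE)[1, ]
  peak_truth <- which(truth * msk == max(truth * msk), arr.ind = TRUE)[1, ]
  expect_true(all(abs(peak - peak_truth) <= 2))
  # a particle close to the field edge with an oversize box is skipped
  s_edge <- s
  s_edge$particles$x <- 30
  sub_edge <- extract_subvolumes(ts, s_edge, box = 24)
  expect_equal(sub_edge$skipped, 1)
  expect_equal(length(sub_edge$boxes), 0)
})

test_that("MRC volumes and stacks round-trip with voxel size and metadata", {
  vol <- render_density(make_phantom_particle(13, 200, 10), c(20, 20, 20), 1.7)
  path <- tempfile(fileext = ".mrc")
  write_mrc(vol, path)
  back <- read_mrc(path)
  expect_equal(dim(back), c(20, 20, 20))
  expect_equal(attr(back, "voxel"), 1.7, tolerance = 1e-6)
  expect_equal(as.numeric(back), as.numeric(vol), tolerance = 1e-6)
  # stack with FEI-style extended header
  meta <- data.frame(index = 1:3, angle = c(0, 30, -30), exposure = 1,
                     cumulative_exposure = 1:3, dose_per_image = 2,
                     accumulated_dose = c(2, 4, 6), defocus = 25000, pixel = 2)
  stack <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  write_mrc(stack, path, voxel = 2, meta = meta)
  back2 <- read_mrc(path)
  m <- attr(back2, "meta")
  expect_equal(m$angle, meta$angle, tolerance = 1e-6)
  expect_equal(m$accumulated_dose, meta$accumulated_dose, tolerance = 1e-6)
  expect_true(file.exists(paste0(path, ".meta.tsv")))
})

test_that("closing the loop at full coverage and high dose recovers the truth", {
  # 180-degree range, ensemble counting statistics emulating a large average:
  # the low-resolution FSC average against the rendered ground truth must
  # reach 0.9
  cfg <- default_config()
  cfg$detector$nx <- 48; cfg$detector$ny <- 48; cfg$detector$pixel_size <- 2
  cfg$simulation$pixel_size <- 2
  cfg$simulation$dose_scale <- 5000
  cfg$simulation$mean_free_path <- 314
  # an ideal phase plate transfers the full band with no CTF zeros, so the
  # loop closes without losing information to contrast inversions
  cfg$lens$defocus <- 0
  cfg$lens$phase_plate_shift <- pi / 2
  cfg$scan$max_tilt <- 90; cfg$scan$mode <- "fixed_count"
  cfg$scan$num_images <- 35
  cfg$beam$flux <- 1; cfg$scan$exposure <- 120 / 35
  geom <- cylinder_geometry(length = 300, radius = 45)
  phantom <- make_phantom_particle(21, 4000, 28)
  smp <- place_particles(new_sample(geom), phantom, count = 1,
                         orientations = "identity")
  ts <- simulate_tilt_series(cfg, smp)
  sub <- extract_subvolumes(ts, smp, box = 48)
  avg <- subtomogram_average(sub$boxes, sub$poses, max_tilt = 90)
  truth <- render_density(phantom, c(48, 48, 48), 2)
  msk <- spherical_mask(c(48, 48, 48), 2, 34, 6)
  summary <- fsc_summary(array(avg * msk, dim(msk)),
                         array(truth * msk, dim(msk)), voxel = 2,
                         qmax = (2 / 3) / (2 * 2))
  expect_gte(summary$fsc_low, 0.9)
})

test_that("FSC curves export to TSV", {
  vol <- render_density(make_phantom_particle(15, 200, 10), c(16, 16, 16), 2)
  curve <- fsc(vol, vol, voxel = 2)
  path <- tempfile(fileext = ".tsv")
  write_fsc(curve, path)
  back <- read.delim(path)
  expect_equal(names(back), c("q", "fsc", "n"))
  expect_equal(back$n, curve$n)
})
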