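test_that("electron wavelength matches the relativistic closed form", {
  expect_equal(electron_wavelength(300), 0.01969, tolerance = 1e-3)
  expect_equal(electron_wavelength(100), 0.03701, tolerance = 1e-3)
  e <- c(80, 100, 200, 300)
  expect_true(all(diff(electron_wavelength(e)) < 0))
})

test_that("projected potential conserves the integrated atom contribution", {
  grid <- grid_spec(32, 32, 2, 5)
  atom <- cryotwin:::new_atomic_model("C", 0, 0, 0)
  total <- function(zpos) {
    geom <- plane_geometry(200, 200, 60)
    s <- place_particles(new_sample(geom), atom,
                         positions = matrix(c(0, 0, zpos), 1),
                         orientations = "identity")
    pot <- project_potential(s, 0, grid)
    sum(pot$slices) * 2^2 # V*A per pixel -> V*A^3
  }
  t1 <- total(0)
  t2 <- total(-22) # different slice
  expect_equal(t1, t2, tolerance = 1e-9)
  expect_equal(t1, 6 * 30, tolerance = 1e-6) # Z * amplitude
})

test_that("empty samples project to zero and co-slice atoms superpose", {
  grid <- grid_spec(32, 32, 2, 5)
  geom <- plane_geometry(200, 200, 40)
  empty <- new_sample(geom)
  expect_true(all(project_potential(empty, 15, grid)$slices == 0))
  one <- place_particles(empty, cryotwin:::new_atomic_model("O", 3, -5, 0),
                         positions = matrix(c(3, -5, 1), 1),
                         orientations = "identity")
  # two identical atoms at the same (x, y), both landing in the same slice
  two <- place_particles(
    empty, cryotwin:::new_atomic_model("O", c(3, 3), c(-5, -5), c(0.4, -0.4)),
    positions = matrix(c(3, -5, 1), 1), orientations = "identity"
  )
  p1 <- project_potential(one, 0, grid)
  p2 <- project_potential(two, 0, grid)
  expect_equal(sum(p2$slices), 2 * sum(p1$slices), tolerance = 1e-9)
  k <- which(apply(p1$slices, 3, sum) > 0)
  expect_equal(p2$slices[, , k], 2 * p1$slices[, , k], tolerance = 1e-9)
})

test_that("beam damage filter follows B = 8 pi^2 D S and damps monotonically", {
  expect_equal(damage_b_factor(1, 0.022), 8 * pi^2 * 0.022)
  expect_equal(damage_b_factor(1, 0.022), 1.737, tolerance = 1e-3)
  s <- thin_atom_sample()
  grid <- grid_spec(32, 32, 2, 5)
  pot <- project_potential(s, 0, grid)
  # zero dose: identity
  expect_equal(apply_beam_damage(pot, 0)$slices, pot$slices)
  # power strictly non-increasing with dose at every q
  d1 <- apply_beam_damage(pot, 10)
  d2 <- apply_beam_damage(pot, 40)
  k <- which.max(apply(pot$slices, 3, sum))
  p0 <- Mod(stats::fft(pot$slices[, , k]))
  p1 <- Mod(stats::fft(d1$slices[, , k]))
  p2 <- Mod(stats::fft(d2$slices[, , k]))
  expect_true(all(p1 <= p0 + 1e-12))
  expect_true(all(p2 <= p1 + 1e-12))
  # slice mean (q = 0) preserved
  expect_equal(mean(d2$slices[, , k]), mean(pot$slices[, , k]))
  # fused filtering in project_potential equals the composition
  fused <- project_potential(s, 0, grid, damage_b = damage_b_factor(25))
  composed <- apply_beam_damage(project_potential(s, 0, grid), 25)
  expect_equal(fused$slices, composed$slices, tolerance = 1e-12)
})

test_that("free-space multislice is unitary over 100 slices", {
  pot <- list(slices = array(0, c(32, 32, 100)),
              interior = array(0, c(32, 32, 100)),
              pixel = 1, slice_thickness = 5, z0 = 0)
  class(pot) <- "potential_slices"
  w <- multislice(pot, table1_beam())
  expect_lt(abs(w$intensity - 1), 1e-6)
  expect_equal(dim(w$psi), c(32, 32))
})

test_that("a weak slice reproduces the weak-phase object approximation", {
  s <- thin_atom_sample()
  grid <- grid_spec(64, 64, 2, 5)
  pot <- project_potential(s, 0, grid, atom_amplitude = 3)
  w <- multislice(pot, table1_beam(), band_limit = FALSE)
  sigma <- interaction_constant(300)
  vproj <- apply(pot$slices, c(1, 2), sum)
  expect_lt(max(sigma * vproj), 0.05)
  wpoa <- 1 + 1i * sigma * vproj
  # remove the free-space propagation phase accumulated after the slice
  expect_lt(max(Mod(Mod(w$psi) - Mod(wpoa))), 0.01)
  expect_lt(abs(w$intensity - 1), 1e-6)
})

test_that("interior attenuation reproduces Beer-Lambert tilt scaling", {
  geom <- plane_geometry(4000, 400, 150)
  s <- new_sample(geom)
  grid <- grid_spec(32, 32, 4, 5)
  mfp <- 314
  ints <- vapply(c(0, 30, 50, 60), function(a) {
    pot <- project_potential(s, a, grid)
    multislice(pot, table1_beam(), mean_free_path = mfp)$intensity
  }, numeric(1))
  expect_true(all(diff(ints) < 0))
  # relative to zero tilt, matches exp((1 - 1/cos a) D0 / mfp)
  expect_equal(ints[4] / ints[1], relative_intensity(60, 150, 314),
               tolerance = 0.02)
})

test_that("CTF has unit envelopes at q = 0 and the documented first zero", {
  ctf <- ctf_evaluate(table1_lens(), table1_beam(), 256, 256, 1)
  expect_equal(ctf$envelope[1, 1], 1)
  expect_equal(ctf$chi[1, 1], 0)
  expect_true(all(abs(ctf$envelope) <= 1 + 1e-12))
  # independent root find of chi(q) = pi on the printed aberration expansion
  lam <- electron_wavelength(300)
  root <- stats::uniroot(function(q) {
    pi * lam * 25000 * q^2 - pi / 2 * 2.7e7 * lam^3 * q^4 - pi
  }, c(1e-4, 0.1))$root
  expect_equal(ctf_first_zero(ctf), root, tolerance = 0.01)
})

test_that("an ideal phase plate transfers |CTF| = envelope at all q", {
  lens <- table1_lens()
  lens$defocus <- 0
  lens$spherical_aberration <- 0
  lens$phase_plate_shift <- pi / 2
  ctf <- ctf_evaluate(lens, table1_beam(), 64, 64, 1)
  expect_equal(abs(ctf$imag), ctf$envelope, tolerance = 1e-12)
})

test_that("identity transfer leaves |psi|^2 unchanged; uniform wave stays uniform", {
  s <- thin_atom_sample()
  pot <- project_potential(s, 0, grid_spec(32, 32, 2, 5))
  w <- multislice(pot, table1_beam())
  lens0 <- list(defocus = 0, spherical_aberration = 0,
                chromatic_aberration = 0, phase_plate_shift = 0)
  beam0 <- table1_beam()
  beam0$energy_spread <- 0; beam0$voltage_spread <- 0
  beam0$current_spread <- 0; beam0$source_spread <- 0
  ctf0 <- ctf_evaluate(lens0, beam0, 32, 32, 2)
  expect_equal(apply_optics(w, ctf0), Mod(w$psi)^2, tolerance = 1e-10)
  flat <- w; flat$psi <- matrix(1 + 0i, 32, 32)
  ctf1 <- ctf_evaluate(table1_lens(), table1_beam(), 32, 32, 2)
  img <- apply_optics(flat, ctf1)
  expect_equal(max(img) - min(img), 0, tolerance = 1e-12)
  # grid mismatch errors
  expect_error(apply_optics(w, ctf_evaluate(table1_lens(), table1_beam(), 16, 16, 2)),
               "grid")
})

test_that("full chain matches the linear-imaging prediction within 2%", {
  s <- thin_atom_sample()
  grid <- grid_spec(64, 64, 2, 5)
  pot <- project_potential(s, 0, grid, atom_amplitude = 1)
  w <- multislice(pot, table1_beam(), band_limit = FALSE)
  ctf <- ctf_evaluate(table1_lens(), table1_beam(), 64, 64, 2)
  img <- apply_optics(w, ctf)
  sigma <- interaction_constant(300)
  vproj <- apply(pot$slices, c(1, 2), sum)
  pred <- 2 * sigma * ctf$imag * stats::fft(vproj)
  obs <- stats::fft(img - mean(img))
  sel <- Mod(pred) > 0.2 * max(Mod(pred))
  expect_lt(max(Mod(obs - pred)[sel] / Mod(pred)[sel]), 0.02)
})

test_that("detector follows Poisson statistics and is seed-deterministic", {
  det <- list(nx = 128, ny = 128, pixel_size = 1,
              dqe = list(dqe0 = 1, falloff = 0))
  flat <- matrix(1, 128, 128)
  counts <- apply_detector(flat, det, dose = 100, seed = 42)
  expect_equal(mean(counts), 100, tolerance = 0.02)
  expect_equal(stats::var(as.vector(counts)), 100, tolerance = 0.05)
  expect_identical(counts, apply_detector(flat, det, dose = 100, seed = 42))
  expect_true(all(apply_detector(flat, det, dose = 0, seed = 1) == 0))
  # DQE(0) scales the expected total counts
  det2 <- list(nx = 128, ny = 128, pixel_size = 1,
               dqe = list(dqe0 = 0.5, falloff = 0))
  exp2 <- apply_detector(flat, det2, dose = 100, poisson = FALSE)
  expect_equal(mean(exp2), 50, tolerance = 1e-9)
})

test_that("tilt series bookkeeping: angles, doses, and dose splitting", {
  cfg <- default_config()
  cfg$detector$nx <- 16; cfg$detector$ny <- 16; cfg$detector$pixel_size <- 4
  cfg$simulation$pixel_size <- 4
  cfg$scan$max_tilt <- 45; cfg$scan$mode <- "fixed_count"
  cfg$scan$num_images <- 5
  cfg$beam$flux <- 2; cfg$scan$exposure <- 1.5
  geom <- plane_geometry(56, 56, 36)
  s <- place_particles(new_sample(geom), make_phantom_particle(3, 80, 10),
                       count = 1, orientations = "identity")
  ts <- simulate_tilt_series(cfg, s)
  expect_equal(dim(ts$images)[3], 5)
  expect_equal(sort(ts$meta$angle), seq(-45, 45, length.out = 5))
  expect_equal(ts$meta$accumulated_dose, ts$meta$index * 3)
  expect_true(all(diff(ts$meta$accumulated_dose) > 0))
  # doubling the image count at constant total dose halves the per-image dose
  cfg2 <- cfg
  cfg2$scan$num_images <- 10
  cfg2$scan$exposure <- cfg$scan$exposure / 2
  ts2 <- simulate_tilt_series(cfg2, s)
  expect_equal(ts2$meta$dose_per_image[1], ts$meta$dose_per_image[1] / 2)
  expect_equal(max(ts2$meta$accumulated_dose), max(ts$meta$accumulated_dose))
})

test_that("beam drift offsets shift the images deterministically", {
  cfg <- default_config()
  cfg$detector$nx <- 24; cfg$detector$ny <- 24; cfg$detector$pixel_size <- 2
  cfg$simulation$pixel_size <- 2
  cfg$scan$max_tilt <- 30; cfg$scan$mode <- "fixed_count"; cfg$scan$num_images <- 3
  cfg$beam$flux <- 200; cfg$scan$exposure <- 1
  geom <- plane_geometry(44, 44, 30)
  s <- place_particles(new_sample(geom), make_phantom_particle(6, 60, 8),
                       count = 1, orientations = "identity")
  still <- simulate_tilt_series(cfg, s)
  cfg$beam$drift <- list(model = "sinusoidal", amplitude = 6, period = 4, seed = 0)
  drifted <- simulate_tilt_series(cfg, s)
  expect_false(identical(still$images, drifted$images))
  expect_identical(drifted$images, simulate_tilt_series(cfg, s)$images)
  cfg$beam$drift <- list(model = "random", amplitude = 4, period = 4, seed = 3)
  expect_false(identical(still$images, simulate_tilt_series(cfg, s)$images))
})
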