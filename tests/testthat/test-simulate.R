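test_that("Guinier prefactor follows the constant-electron-count arithmetic", {
  const <- guinier_constants()
  # Ne - rho_b * Vp = 9900 - 0.34 * 23000 = 2080 electrons
  p <- absolute_pattern(0, const$Rg0, const$Vp0, const,
                        background = function(q) 0 * q)
  expect_equal(p$I, 2080^2)
  # doubling Rg at fixed Vp: intensity ratio is exp(-q^2 (Rg2^2 - Rg1^2)/3)
  q <- seq(0.01, 0.1, by = 0.01)
  a <- absolute_pattern(q, 17, 23000, const, function(q) 0 * q)
  b <- absolute_pattern(q, 34, 23000, const, function(q) 0 * q)
  expect_equal(b$I / a$I, exp(-q^2 * (34^2 - 17^2) / 3), tolerance = 1e-12)
  expect_error(absolute_pattern(q, 17, -5, const), "Vp")
  # background is strictly positive over the normalization window
  qw <- seq(1.3, 1.5, by = 0.01)
  expect_true(all(default_background(qw) > 0))
})

test_that("noiseless frames reproduce the model curve exactly", {
  sched <- delay_schedule(delays = c(-1, 2, 5), repetitions = 4)
  run <- simulate_run(sched, noise = noise_model(sigma_rel = 0,
                                                 outlier_fraction = 0),
                      seed = 3)
  p <- trajectory_params()
  const <- guinier_constants()
  for (d in c(-1, 2, 5)) {
    rows <- which(run$manifest$delay == d)
    truth <- absolute_pattern(run$q, rg_trajectory(d, p),
                              vp_trajectory(d, p), const)$I
    for (i in rows) expect_equal(run$I[i, ], truth, tolerance = 1e-14)
  }
})

test_that("simulation is reproducible from its seed", {
  sched <- delay_schedule(delays = c(0, 1), repetitions = 5)
  a <- simulate_run(sched, seed = 42)
  b <- simulate_run(sched, seed = 42)
  expect_identical(a$I, b$I)
  expect_identical(a$manifest, b$manifest)
  c <- simulate_run(sched, seed = 43)
  expect_false(identical(a$I, c$I))
  # the global RNG stream is left untouched
  set.seed(99); x1 <- rnorm(1)
  set.seed(99); invisible(simulate_run(sched, seed = 1)); x2 <- rnorm(1)
  expect_identical(x1, x2)
})

test_that("corrupted shots are planted at the exact scheduled rate", {
  sched <- delay_schedule(delays = c(0, 3), repetitions = 50)
  run <- simulate_run(sched, noise = noise_model(outlier_fraction = 0.2),
                      seed = 5)
  m <- run$manifest
  for (d in c(0, 3)) {
    expect_identical(sum(m$corrupted[m$delay == d & !m$is_reference]), 10L)
  }
  expect_false(any(m$corrupted[m$is_reference]))
})

test_that("reference frames are interleaved within reach of every frame", {
  sched <- delay_schedule(delays = seq(0, 5), repetitions = 10,
                          reference_interval = 7)
  run <- simulate_run(sched, seed = 2)
  m <- run$manifest
  expect_gt(sum(m$is_reference), 0)
  expect_true(all(m$delay[m$is_reference] == sched$reference_delay))
  pairs <- pair_with_reference(m$is_reference)
  expect_true(all(abs(pairs$frame - pairs$reference) <= 4))
})

test_that("a run written to disk reads back identically", {
  sched <- delay_schedule(delays = c(0, 2), repetitions = 3)
  run <- simulate_run(sched, q_grid = seq(0.02, 2, by = 0.02), seed = 8)
  dir <- withr::local_tempdir()
  write_run(run, dir)
  run2 <- read_run(dir)
  expect_equal(run2$I, run$I, tolerance = 1e-15)
  expect_equal(run2$manifest$delay, run$manifest$delay)
  expect_equal(run2$manifest$corrupted, run$manifest$corrupted)
})

test_that("rendered images azimuthally average back to the pattern", {
  # a detector fine enough that every annulus holds many pixels
  g <- experiment_geometry(photon_energy_keV = 9, distance_cm = 16.8,
                           pixel_size_um = 600,
                           detector_shape = c(256, 256))
  q <- seq(0.001, 4, by = 0.002)
  pat <- pattern1d(q, 1e3 * exp(-q) + 100, meta = list(delay = 1))
  img <- render_image(pat, g)  # photon_scale = Inf: no noise
  rec <- azimuthal_average(img, q_bins = 60)
  truth <- approx(pat$q, pat$I, xout = rec$q)$y
  expect_lt(max(abs(rec$I / truth - 1)), 0.005)
  # isotropy: pixels at mirrored positions are identical
  expect_equal(img$counts[10, 20], img$counts[20, 10], tolerance = 1e-12)
  expect_equal(img$counts, img$counts[256:1, ], tolerance = 1e-12)
  # zero pattern renders to a zero image
  z <- render_image(pattern1d(q, 0 * q), g)
  expect_true(all(z$counts == 0))
  # pattern too narrow for the detector
  expect_error(render_image(pattern1d(seq(0.5, 1, 0.01), rep(1, 51)), g),
               "does not cover")
})

test_that("observable-level series generator is deterministic and labelled", {
  s1 <- simulate_delay_series(seed = 7)
  s2 <- simulate_delay_series(seed = 7)
  expect_identical(s1, s2)
  expect_equal(attr(s1, "observable"), "dRg")
  expect_true(all(s1$error == 0.1))
  sv <- simulate_delay_series(observable = "dVp", seed = 7)
  expect_true(all(sv$error == 10))
  # noise-free check of the underlying truth
  s0 <- simulate_delay_series(noise_sd = 1e-12, seed = 1)
  p <- trajectory_params()
  expect_equal(s0$value, rg_trajectory(s0$delay, p) - p$Rg0,
               tolerance = 1e-9)
})
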