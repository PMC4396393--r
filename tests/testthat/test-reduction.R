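test_that("window normalization scales to unit mean and is idempotent", {
  q <- seq(0.02, 2, by = 0.005)
  p <- pattern1d(q, 7e5 * exp(-q) + 1e4, abs(rnorm(length(q), 100, 10)))
  n1 <- normalize_pattern(p)
  w <- q >= 1.3 & q <= 1.5
  expect_equal(mean(n1$I[w]), 1, tolerance = 1e-12)
  # already-normalized input is unchanged
  n2 <- normalize_pattern(n1)
  expect_equal(n2$I, n1$I, tolerance = 1e-12)
  # global scale invariance
  p7 <- pattern1d(q, 7 * p$I, 7 * p$sigma)
  n7 <- normalize_pattern(p7)
  expect_equal(n7$I, n1$I, tolerance = 1e-12)
  expect_equal(n7$sigma, n1$sigma, tolerance = 1e-12)
  # scale factor is recorded and compounds
  expect_equal(n7$meta$norm_scale / n1$meta$norm_scale, 7,
               tolerance = 1e-12)
  # two frames differing only by a global scale difference to exactly zero
  expect_equal(max(abs(n7$I - n1$I)), 0, tolerance = 1e-14)
  expect_error(normalize_pattern(pattern1d(q, -p$I)), "non-positive")
  expect_error(normalize_pattern(pattern1d(seq(0.02, 1, 0.005),
                                           rep(1, 197))),
               "outside")
  expect_error(norm_window(0.05, 0.1), "half_width")
})

test_that("laser-on frames pair with the nearest reference, earlier on ties", {
  # frames [R, a, b, R, c]: a is nearest the first reference, b the second
  pr <- pair_with_reference(c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(pr$frame, c(2, 3, 5))
  expect_equal(pr$reference, c(1, 4, 4))
  # frames [R, a, R]: a equidistant, the earlier reference wins the tie
  pr_tie <- pair_with_reference(c(TRUE, FALSE, TRUE))
  expect_equal(pr_tie$reference, 1)
  # a single reference catches everything
  pr1 <- pair_with_reference(c(FALSE, TRUE, FALSE, FALSE))
  expect_true(all(pr1$reference == 2))
  expect_error(pair_with_reference(c(FALSE, FALSE)), "no reference")
})

test_that("chi2 screen accepts identical frames and rejects planted shots", {
  nq <- 80
  dI <- matrix(rep(sin(1:nq / 5), 6), 6, nq, byrow = TRUE)
  sg <- matrix(1, 6, nq)
  rep0 <- chi2_screen(dI, sg, threshold = 0.5)
  expect_equal(rep0$chi2red, rep(0, 6))
  expect_length(rep0$rejected, 0)

  run <- simulate_run(delay_schedule(delays = 5, repetitions = 50),
                      seed = 11)
  red <- reduce_run(run)
  man <- run$manifest
  pairs <- pair_with_reference(man$is_reference)
  planted <- which(man$corrupted[pairs$frame])
  expect_identical(sort(red$reports[[1]]$rejected), sort(planted))
  expect_equal(red$reports[[1]]$rejection_fraction, 0.2)

  expect_error(chi2_screen(dI[1:2, ], sg[1:2, ]), "at least 3")
  expect_error(chi2_screen(dI, 0 * sg), "sigma")
})

test_that("screening is invariant under frame permutation", {
  set.seed(21)
  nq <- 60
  dI <- matrix(rnorm(20 * nq), 20, nq)
  dI[c(4, 17), ] <- dI[c(4, 17), ] + 3
  sg <- matrix(1, 20, nq)
  rep1 <- chi2_screen(dI, sg)
  perm <- sample(20)
  rep2 <- chi2_screen(dI[perm, ], sg)
  expect_setequal(perm[rep2$rejected], rep1$rejected)
})

test_that("averaging follows the 1/sqrt(n) law", {
  # single frame passes through with its own sigma
  q <- seq(0.1, 1, by = 0.1)
  one <- average_differences(matrix(1:10, 1), q,
                             frame_sigma = rep(0.5, 10))
  expect_equal(one$I, 1:10)
  expect_equal(one$sigma, rep(0.5, 10))
  expect_equal(one$meta$n_accepted, 1)
  # n identical frames: same mean, vanishing spread
  many <- average_differences(matrix(rep(1:10, 5), 5, byrow = TRUE), q)
  expect_equal(many$I, 1:10)
  expect_true(all(many$sigma < 1e-14))
  # Monte-Carlo: sem at n = 10 vs n = 40 scales as sqrt(4) within 20%
  set.seed(31)
  sem_of <- function(n) {
    mean(replicate(40, {
      avg <- average_differences(matrix(rnorm(n * 10), n), q)
      mean(avg$sigma)
    }))
  }
  expect_equal(sem_of(10) / sem_of(40), 2, tolerance = 0.2)
  expect_error(average_differences(matrix(0, 0, 10), q), "no accepted")
})

test_that("azimuthal averaging handles constant, masked and empty inputs", {
  g <- tiny_geometry()
  img <- detector_image(matrix(3.7, 64, 64), g)
  pat <- azimuthal_average(img, q_bins = 30)
  expect_true(all(abs(pat$I - 3.7) < 1e-12))
  expect_true(all(pat$sigma < 1e-12))
  mask <- matrix(FALSE, 64, 64)
  expect_error(azimuthal_average(detector_image(matrix(1, 64, 64), g,
                                                mask = mask)),
               "masked")
})

test_that("reduction is equivariant under a global intensity scale", {
  run <- simulate_run(delay_schedule(delays = c(1, 4), repetitions = 8),
                      seed = 13)
  red1 <- reduce_run(run)
  run$I <- run$I * 37
  run$sigma <- run$sigma * 37
  red2 <- reduce_run(run)
  for (k in seq_along(red1$patterns)) {
    expect_equal(red2$patterns[[k]]$I, red1$patterns[[k]]$I,
                 tolerance = 1e-12)
    expect_equal(red2$patterns[[k]]$sigma, red1$patterns[[k]]$sigma,
                 tolerance = 1e-12)
  }
})

test_that("noiseless reduction reproduces the analytic difference model", {
  sched <- delay_schedule(delays = c(-3, 1, 3, 5, 100), repetitions = 3)
  run <- simulate_run(sched, noise = noise_model(sigma_rel = 0,
                                                 outlier_fraction = 0),
                      seed = 7)
  red <- reduce_run(run, screen = FALSE)
  p <- trajectory_params()
  const <- guinier_constants()
  for (k in seq_along(red$patterns)) {
    pat <- red$patterns[[k]]
    d <- pat$meta$delay
    if (d < 1) next  # pre-pump: no signal to compare against
    truth <- diff_guinier_model(run$q, rg_trajectory(d, p) - p$Rg0,
                                vp_trajectory(d, p) - p$Vp0,
                                const = const)
    rec <- pat$I * pat$meta$norm_scale
    expect_lt(max(abs(rec - truth)) / max(abs(truth)), 1e-3)
  }
  # the pre-pump delay (-3 ps, >10 IRF widths before t0) differences to
  # numerically nothing
  pre <- red$patterns[[1]]
  expect_lt(max(abs(pre$I * pre$meta$norm_scale)),
            1e-8 * max(run$I))
})
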