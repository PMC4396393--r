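test_that("Guinier intensity obeys its closed form", {
  const <- guinier_constants()
  expect_equal(guinier_intensity(0, 17, 23000, const), 2080^2)
  # log-linearity in q^2 with slope -Rg^2/3
  q <- seq(0.01, 0.1, by = 0.005)
  lnI <- log(guinier_intensity(q, 21, 23000, const))
  slope <- coef(lm(lnI ~ I(q^2)))[[2]]
  expect_equal(slope, -21^2 / 3, tolerance = 1e-10)
  expect_error(guinier_intensity(0.05, 17, 40000, const), "contrast")
  expect_error(guinier_intensity(0.05, -1, 23000, const), "Rg")
  expect_error(guinier_constants(Ne = 100, Vp0 = 23000), "contrast|rho_b")
})

test_that("difference model matches a brute-force two-state evaluation", {
  const <- guinier_constants()
  q <- seq(0.005, 0.15, length.out = 400)
  # independent evaluation from the printed expression, written out long-hand
  brute <- function(q, dRg, dVp) {
    two_state <- function(Rg, Vp) {
      rho_p <- const$Ne / Vp
      ((rho_p - const$rho_b) * Vp)^2 * exp(-q^2 * Rg^2 / 3)
    }
    two_state(const$Rg0 + dRg, const$Vp0 + dVp) -
      two_state(const$Rg0, const$Vp0)
  }
  expect_equal(diff_guinier_model(q, 1.0, 220, const = const),
               brute(q, 1.0, 220), tolerance = 1e-12)
  # coincident states difference to exactly zero
  expect_true(all(diff_guinier_model(q, 0, 0, const = const) == 0))
  # pure mass redistribution: zero at q = 0, negative beyond
  d <- diff_guinier_model(c(0, q), 1.0, 0, const = const)
  expect_equal(d[1], 0)
  expect_true(all(d[-1] < 0))
  # expansion lowers the forward scattering
  expect_lt(diff_guinier_model(0, 0, 220, const = const), 0)
  expect_equal(sign(diff_guinier_model(0, 0, 220, const = const)),
               sign((const$Ne - const$rho_b * (const$Vp0 + 220))^2 -
                      (const$Ne - const$rho_b * const$Vp0)^2))
})

test_that("noiseless difference patterns are fitted back exactly", {
  const <- guinier_constants()
  q <- seq(0.01, 0.5, by = 0.002)
  dI <- diff_guinier_model(q, 1.0, 220, const = const)
  pat <- pattern1d(q, dI, rep(1, length(q)), meta = list(delay = 5))
  f <- fit_difference(pat, const = const)
  expect_lt(abs(coef(f)[["dRg"]] - 1.0), 1e-3 * 1.0)
  expect_lt(abs(coef(f)[["dVp"]] - 220) / 220, 1e-3)
  # far from converged init, same optimum
  f2 <- fit_difference(pat, const = const, init = c(dRg = 0.5, dVp = 50))
  expect_equal(coef(f2), coef(f), tolerance = 1e-6)
  # electron count is conserved between the two fitted states by
  # construction: the model at the optimum matches the data
  expect_lt(max(abs(predict(f) - f$data$dI)) / max(abs(dI)), 1e-6)
})

test_that("a zero pattern fits to zero within one standard deviation", {
  q <- seq(0.01, 0.12, by = 0.002)
  pat <- pattern1d(q, rep(0, length(q)), rep(50, length(q)))
  f <- fit_difference(pat)
  expect_lt(abs(coef(f)[["dRg"]]), f$se[["dRg"]])
  expect_lt(abs(coef(f)[["dVp"]]), f$se[["dVp"]])
})

test_that("free-amplitude fits recover a scaled pattern", {
  const <- guinier_constants()
  q <- seq(0.01, 0.3, by = 0.002)
  dI <- 0.4 * diff_guinier_model(q, 1.0, 220, const = const)
  pat <- pattern1d(q, dI, rep(1, length(q)))
  f <- fit_difference(pat, const = const, free_alpha = TRUE,
                      init = c(dRg = 0.8, dVp = 180))
  expect_equal(coef(f)[["alpha"]], 0.4, tolerance = 1e-3)
  expect_equal(coef(f)[["dRg"]], 1.0, tolerance = 1e-2)
})

test_that("replicate fits are unbiased with calibrated errors", {
  # full simulate -> reduce -> fit chain at the default noise
  p <- trajectory_params()
  const <- guinier_constants()
  one_rep <- function(seed) {
    run <- simulate_run(delay_schedule(delays = 100, repetitions = 50),
                        noise = noise_model(outlier_fraction = 0),
                        params = p, seed = seed)
    f <- fit_difference(reduce_run(run)$patterns[[1]], const = const)
    c(coef(f), f$se)
  }
  res <- t(vapply(1:200, one_rep, numeric(4)))
  truth <- c(rg_trajectory(100, p) - p$Rg0, vp_trajectory(100, p) - p$Vp0)
  bias <- colMeans(res[, 1:2]) - truth
  spread <- apply(res[, 1:2], 2, sd)
  # bias below 10% of the replicate scatter for both observables
  expect_lt(abs(bias[1]) / spread[1], 0.1)
  expect_lt(abs(bias[2]) / spread[2], 0.1)
  # covariance errors agree with the replicate scatter within 30%
  expect_lt(abs(mean(res[, 3]) / spread[1] - 1), 0.3)
  expect_lt(abs(mean(res[, 4]) / spread[2] - 1), 0.3)
})

test_that("series fitting preserves per-delay independence and failures", {
  const <- guinier_constants()
  q <- seq(0.01, 0.5, by = 0.005)
  mk <- function(dRg, dVp, delay) {
    pattern1d(q, diff_guinier_model(q, dRg, dVp, const = const),
              rep(1, length(q)), meta = list(delay = delay))
  }
  pats <- list(mk(0.5, 100, 2), mk(1.0, 220, 8), mk(0.2, 40, 0.5))
  ser <- fit_series(pats, const = const)
  expect_equal(ser$delay, c(0.5, 2, 8))  # sorted by delay
  expect_equal(ser$dRg, c(0.2, 0.5, 1.0), tolerance = 1e-4)
  # identical to one-by-one fits
  solo <- fit_difference(pats[[2]], const = const)
  expect_equal(ser$dVp[ser$delay == 8], coef(solo)[["dVp"]],
               tolerance = 1e-12)
  # all-zero patterns give a flat series at zero
  zeros <- lapply(c(1, 2, 3), function(d) {
    pattern1d(q, rep(0, length(q)), rep(1, length(q)),
              meta = list(delay = d))
  })
  zs <- fit_series(zeros, const = const)
  expect_true(all(abs(zs$dRg) < 1e-6))
  # a broken pattern is recorded, not dropped
  bad <- pattern1d(q[1:5], rep(0, 5), rep(1, 5), meta = list(delay = 9))
  ser2 <- fit_series(c(pats, list(bad)), const = const)
  expect_equal(nrow(ser2), 4)
  expect_false(ser2$ok[ser2$delay == 9])
  s <- delay_series(ser2, "dRg")
  expect_equal(nrow(s), 3)  # failed delay excluded from the series
})
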