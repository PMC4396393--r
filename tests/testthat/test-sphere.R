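# independent real-axis oracle: the free elastic sphere breathing-mode
# (Lamb) equation solved by bisection
lamb_roots <- function(material, n = 4, upper = 13) {
  eta2 <- (material$v_t / material$v_l)^2
  f <- function(s) {
    sin(s) / s - 4 * eta2 * (sin(s) / s^2 - cos(s) / s) / s
  }
  ss <- seq(0.05, upper, by = 1e-3)
  v <- f(ss)
  roots <- c()
  for (i in seq_len(length(ss) - 1)) {
    if (v[i] * v[i + 1] < 0) {
      roots <- c(roots, uniroot(f, c(ss[i], ss[i + 1]), tol = 1e-14)$root)
    }
  }
  head(roots, n)
}

test_that("impedance vanishes in vacuum and has real-coefficient symmetry", {
  mat <- mb_sphere_material()
  vac <- acoustic_medium(d_m = 0)
  s <- complex(real = c(1, 3.2, 7), imaginary = c(-0.1, -0.5, -1))
  expect_true(all(acoustic_impedance(s, mat, vac) == 0))
  water <- acoustic_medium()
  # reflection through the imaginary axis conjugates the impedance and
  # the characteristic function, so roots come in (s, -s*) pairs
  expect_equal(acoustic_impedance(-Conj(s), mat, water),
               Conj(acoustic_impedance(s, mat, water)), tolerance = 1e-13)
  expect_equal(sphere_characteristic(-Conj(s), mat, water),
               Conj(sphere_characteristic(s, mat, water)),
               tolerance = 1e-13)
  expect_error(acoustic_impedance(0 + 0i, mat, water), "non-zero")
})

test_that("impedance is finite and smooth along a lossy scan line", {
  mat <- mb_sphere_material()
  water <- acoustic_medium()
  s <- complex(real = seq(0.5, 10, length.out = 400), imaginary = -0.2)
  Z <- acoustic_impedance(s, mat, water)
  expect_true(all(is.finite(Re(Z)) & is.finite(Im(Z))))
  # no jumps: consecutive relative steps stay small
  expect_lt(max(Mod(diff(Z))) / max(Mod(Z)), 0.05)
})

test_that("characteristic values are bit-reproducible", {
  mat <- mb_sphere_material()
  water <- acoustic_medium()
  s <- complex(real = 2.34, imaginary = -0.56)
  expect_identical(sphere_characteristic(s, mat, water),
                   sphere_characteristic(s, mat, water))
})

test_that("vacuum modes match the free-sphere oracle and never damp", {
  mat <- mb_sphere_material()
  modes <- find_modes(mat, acoustic_medium(d_m = 0), n_modes = 3)
  oracle <- lamb_roots(mat, n = 3)
  expect_equal(modes$s_re, oracle, tolerance = 1e-8)
  expect_true(all(abs(modes$s_im) < 1e-10))
  expect_true(all(abs(modes$omega_im) < 1e-8 * modes$omega_re))
  expect_true(all(modes$residual < 1e-10))
})

test_that("frequencies scale as 1/R at fixed material", {
  m1 <- mb_sphere_material()
  m2 <- mb_sphere_material(R = m1$R / 2)
  water <- acoustic_medium()
  a <- find_modes(m1, water, n_modes = 3)
  b <- find_modes(m2, water, n_modes = 3)
  expect_equal(b$omega_re / a$omega_re, rep(2, 3), tolerance = 1e-5)
  expect_equal(b$period_ps, a$period_ps / 2, tolerance = 1e-5)
  expect_equal(b$s_re, a$s_re, tolerance = 1e-7)  # s is scale-free
})

test_that("roots are stable against the scan resolution", {
  mat <- mb_sphere_material()
  water <- acoustic_medium()
  a <- find_modes(mat, water, n_modes = 3, grid_n = c(600, 150))
  b <- find_modes(mat, water, n_modes = 3, grid_n = c(401, 97))
  expect_equal(a$s_re, b$s_re, tolerance = 1e-8)
  expect_equal(a$s_im, b$s_im, tolerance = 1e-8)
})

test_that("roots move continuously from the vacuum limit into the fluid", {
  mat <- mb_sphere_material()
  free_root <- lamb_roots(mat, n = 1)
  dm <- c(0, 10, 100, 1000)
  roots <- vapply(dm, function(d) {
    m <- find_modes(mat, acoustic_medium(d_m = d), n_modes = 1)
    complex(real = m$s_re, imaginary = m$s_im)
  }, complex(1))
  # light loading stays near the free root; |Im| grows monotonically
  expect_equal(Re(roots[1]), free_root, tolerance = 1e-8)
  expect_lt(Mod(roots[2] - roots[1]), 0.05)
  expect_true(all(diff(abs(Im(roots))) > 0))
  expect_true(all(Im(roots[-1]) < 0))
})

test_that("SI and Angstrom/ps unit paths agree", {
  mat <- mb_sphere_material()
  modes <- find_modes(mat, acoustic_medium(), n_modes = 3)
  s <- complex(real = modes$s_re, imaginary = modes$s_im)
  omega_SI <- s * mat$v_l / (mat$R * 1e-10)       # rad/s
  period_SI_ps <- 2 * pi / Re(omega_SI) * 1e12
  tau_SI_ps <- -1 / Im(omega_SI) * 1e12
  expect_equal(modes$period_ps, period_SI_ps, tolerance = 1e-14)
  expect_equal(modes$tau_D_ps, tau_SI_ps, tolerance = 1e-14)
})

test_that("material and medium invariants are enforced", {
  expect_error(sphere_material(1000, 1500, 1350, 20))  # v_t >= v_l
  expect_error(sphere_material(2000, 1000, -1, 20))
  expect_error(acoustic_medium(d_m = -1))
  m <- find_modes(mb_sphere_material(), acoustic_medium(), n_modes = 3)
  expect_equal(m$mode, 1:3)
  expect_true(all(diff(m$omega_re) > 0))
  expect_warning(find_modes(mb_sphere_material(), acoustic_medium(),
                            n_modes = 50),
                 "requested modes")
})
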