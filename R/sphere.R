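#' Elastic sphere and surrounding medium
#'
#' Material parameters of the homogeneous elastic sphere standing in for
#' the protein, and of the fluid surrounding it. The default material is a
#' reconstructed myoglobin-like parameter set (see [mb_sphere_material()]).
#'
#' @param v_l longitudinal sound speed in the sphere, m/s.
#' @param v_t transverse sound speed in the sphere, m/s (0 < v_t < v_l).
#' @param d_P sphere mass density, kg/m^3.
#' @param R sphere radius, Angstrom.
#' @return an object of class `"sphere_material"`.
#' @export
sphere_material <- function(v_l, v_t, d_P, R) {
  stopifnot(v_l > 0, v_t > 0, v_t < v_l, d_P > 0, R > 0)
  structure(list(v_l = v_l, v_t = v_t, d_P = d_P, R = R),
            class = "sphere_material")
}

#' @rdname sphere_material
#' @param d_m medium mass density, kg/m^3 (0 = vacuum).
#' @param v_m medium sound speed, m/s.
#' @export
acoustic_medium <- function(d_m = 1000, v_m = 1483) {
  stopifnot(d_m >= 0, v_m > 0)
  structure(list(d_m = d_m, v_m = v_m), class = "acoustic_medium")
}

#' Reconstructed myoglobin sphere parameters
#'
#' Synthetic stand-in parameter set for a myoglobin-sized elastic sphere
#' in water, assembled from standard protein acoustics values: mass
#' density 1350 kg/m^3, longitudinal sound speed 2000 m/s (the ~20 A/ps
#' strain propagation speed observed in the protein), transverse speed
#' half the longitudinal one (Poisson ratio 1/3), and the radius of the
#' uniform sphere with the protein's 17 A radius of gyration,
#' \eqn{R = \sqrt{5/3} R_g \approx 21.95} A. Every value is overridable.
#'
#' @param ... overrides passed to [sphere_material()].
#' @return a `"sphere_material"`.
#' @export
mb_sphere_material <- function(...) {
  args <- list(v_l = 2000, v_t = 1000, d_P = 1350, R = sqrt(5 / 3) * 17)
  over <- list(...)
  args[names(over)] <- over
  do.call(sphere_material, args)
}

# complex spherical Bessel functions of order 0 and 1
.sph_j0 <- function(z) sin(z) / z
.sph_j1 <- function(z) sin(z) / z^2 - cos(z) / z

#' Acoustic radiation impedance of a pulsating sphere
#'
#' Specific acoustic impedance (pressure over radial velocity) seen by the
#' sphere surface radiating an outgoing monopole wave into the medium:
#' \deqn{Z(s) = d_m v_m \frac{i k_m R}{i k_m R - 1}, \qquad k_m = \omega/v_m,}
#' in the \eqn{e^{-i\omega t}} time convention, so lossy-medium
#' eigenfrequencies have negative imaginary part. For a vacuum
#' (`d_m = 0`) the impedance vanishes: no radiation loading.
#'
#' @param s complex normalized frequency \eqn{s = \omega R / v_l}
#'   (vectorised); must be non-zero.
#' @param material a [sphere_material()].
#' @param medium an [acoustic_medium()].
#' @return complex impedance in SI units (Pa s / m); non-finite values at
#'   poles of the radial function are returned as-is (flagged `NaN`/`Inf`).
#' @export
acoustic_impedance <- function(s, material, medium) {
  stopifnot(inherits(material, "sphere_material"),
            inherits(medium, "acoustic_medium"))
  if (any(s == 0)) stop("s must be non-zero")
  x <- s * material$v_l / medium$v_m  # k_m R
  medium$d_m * medium$v_m * (1i * x) / (1i * x - 1)
}

#' Characteristic function of the fluid-loaded breathing mode
#'
#' The spheroidal angular-order-0 (breathing) eigenfrequencies of a
#' homogeneous elastic sphere radiating into a fluid satisfy
#' \deqn{d_P v_l^2 j_0(s) - 4 d_P v_t^2 \frac{j_1(s)}{s}
#'   - i v_l Z(s) j_1(s) = 0,}
#' which couples the sphere's elastic surface traction (the classical
#' free-sphere terms) to the monopole radiation impedance of the medium.
#' The value returned is normalized by \eqn{d_P v_l^2}. With `d_m = 0`
#' the equation reduces to the free elastic sphere breathing-mode
#' (Lamb) equation, whose roots are real.
#'
#' @inheritParams acoustic_impedance
#' @return complex residual (zero exactly at eigenfrequencies).
#' @export
sphere_characteristic <- function(s, material, medium) {
  Z <- acoustic_impedance(s, material, medium)
  eta2 <- (material$v_t / material$v_l)^2
  .sph_j0(s) - 4 * eta2 * .sph_j1(s) / s -
    1i * Z * .sph_j1(s) / (material$d_P * material$v_l)
}

# Muller's method for a complex root near s0
.muller <- function(fn, s0, tol = 1e-13, maxit = 80) {
  h <- 1e-4 * max(1, Mod(s0))
  x <- c(s0 - h, s0, s0 + h)
  f <- vapply(x, fn, complex(1))
  for (it in seq_len(maxit)) {
    q <- (x[3] - x[2]) / (x[2] - x[1])
    A <- q * f[3] - q * (1 + q) * f[2] + q^2 * f[1]
    B <- (2 * q + 1) * f[3] - (1 + q)^2 * f[2] + q^2 * f[1]
    C <- (1 + q) * f[3]
    disc <- sqrt(B^2 - 4 * A * C)
    den1 <- B + disc; den2 <- B - disc
    den <- if (Mod(den1) >= Mod(den2)) den1 else den2
    if (Mod(den) == 0) return(list(root = x[3], ok = FALSE))
    xn <- x[3] - (x[3] - x[2]) * 2 * C / den
    fn_new <- fn(xn)
    if (!is.finite(Re(fn_new)) || !is.finite(Im(fn_new))) {
      return(list(root = x[3], ok = FALSE))
    }
    x <- c(x[2], x[3], xn)
    f <- c(f[2], f[3], fn_new)
    if (Mod(xn - x[2]) < tol * max(1, Mod(xn)) && Mod(fn_new) < 1e-10) {
      return(list(root = xn, ok = TRUE, residual = Mod(fn_new)))
    }
  }
  list(root = x[3], ok = Mod(f[3]) < 1e-10, residual = Mod(f[3]))
}

#' Locate breathing modes of the fluid-loaded elastic sphere
#'
#' Finds complex roots of [sphere_characteristic()] by a coarse grid scan
#' of the log-modulus over a box in the lower-half complex s-plane
#' followed by Muller refinement of every local minimum, deduplication,
#' and conversion to physical units: \eqn{\omega = s v_l / R} (rad/ps),
#' period \eqn{= 2\pi/\mathrm{Re}\,\omega}, damping time
#' \eqn{\tau_D = -1/\mathrm{Im}\,\omega}. Modes are sorted by increasing
#' real frequency. For a vacuum medium the roots are real and the damping
#' time is infinite.
#'
#' @param material a [sphere_material()].
#' @param medium an [acoustic_medium()].
#' @param n_modes number of modes to return (default 3).
#' @param re_range,im_range search box for `s` (defaults `c(0.1, 12)` and
#'   `c(-3, 1e-4)`; the sliver above the real axis admits the lossless
#'   real roots).
#' @param grid_n grid resolution `c(n_re, n_im)` (default `c(600, 150)`).
#' @param dedup_tol roots closer than this (in s) are merged.
#' @param residual_tol refined roots with |characteristic| above this are
#'   discarded with a warning.
#' @return an object of class `"sphere_modes"`: data frame with columns
#'   `mode`, `s_re`, `s_im`, `omega_re`, `omega_im` (rad/ps), `period_ps`,
#'   `tau_D_ps`, `residual`; material and medium kept as attributes.
#' @export
find_modes <- function(material, medium = acoustic_medium(),
                       n_modes = 3, re_range = c(0.1, 12),
                       im_range = c(-3, 1e-4), grid_n = c(600, 150),
                       dedup_tol = 1e-6, residual_tol = 1e-10) {
  stopifnot(n_modes >= 1)
  fn <- function(s) sphere_characteristic(s, material, medium)
  re <- seq(re_range[1], re_range[2], length.out = grid_n[1])
  im <- seq(im_range[1], im_range[2], length.out = grid_n[2])
  S <- outer(re, im, function(a, b) complex(real = a, imaginary = b))
  val <- matrix(Mod(fn(as.vector(S))), nrow(S), ncol(S))
  val[!is.finite(val)] <- Inf

  # local minima over the 8-neighborhood (interior + box edges)
  nr <- nrow(val); nc <- ncol(val)
  pad <- matrix(Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- val
  is_min <- matrix(TRUE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_min <- is_min &
      (val <= pad[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)])
  }
  cand <- S[is_min & is.finite(val)]

  roots <- complex(0)
  residuals <- numeric(0)
  for (s0 in cand) {
    ans <- .muller(fn, s0)
    if (!ans$ok) next
    r <- ans$root
    # vibrational modes only: purely relaxational (overdamped) solutions
    # near the imaginary axis are excluded by the box's lower Re(s) edge
    if (Re(r) < re_range[1] || Re(r) > re_range[2] + 0.5) next
    if (Im(r) > 0.01) next  # physical roots lie on or below the real axis
    if (ans$residual > residual_tol) next
    if (length(roots) && any(Mod(roots - r) < dedup_tol)) next
    roots <- c(roots, r)
    residuals <- c(residuals, ans$residual)
  }
  ord <- order(Re(roots))
  roots <- roots[ord]; residuals <- residuals[ord]
  if (length(roots) < n_modes) {
    warning("found only ", length(roots), " of ", n_modes,
            " requested modes in the search box")
  } else {
    roots <- roots[seq_len(n_modes)]
    residuals <- residuals[seq_len(n_modes)]
  }

  v_l_Aps <- material$v_l * 0.01           # m/s -> Angstrom/ps
  omega <- roots * v_l_Aps / material$R    # rad/ps
  tau_D <- ifelse(Im(omega) < 0, -1 / Im(omega), Inf)
  out <- data.frame(mode = seq_along(roots),
                    s_re = Re(roots), s_im = Im(roots),
                    omega_re = Re(omega), omega_im = Im(omega),
                    period_ps = 2 * pi / Re(omega),
                    tau_D_ps = tau_D,
                    residual = residuals)
  structure(out, material = material, medium = medium,
            class = c("sphere_modes", "data.frame"))
}

#' @export
print.sphere_modes <- function(x, ...) {
  m <- attr(x, "material"); md <- attr(x, "medium")
  cat(sprintf(paste0("Breathing modes of an elastic sphere (R = %g A, ",
                     "v_l = %g m/s, v_t = %g m/s, d_P = %g kg/m^3)\n"),
              m$R, m$v_l, m$v_t, m$d_P))
  cat(sprintf("  medium: d_m = %g kg/m^3, v_m = %g m/s\n", md$d_m, md$v_m))
  df <- as.data.frame(x)
  df$period_ps <- signif(df$period_ps, 4)
  df$tau_D_ps <- signif(df$tau_D_ps, 4)
  print(df[, c("mode", "period_ps", "tau_D_ps", "residual")],
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.sphere_modes <- function(object, ...) {
  as.data.frame(object)[, c("mode", "period_ps", "tau_D_ps")]
}
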