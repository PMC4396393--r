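# Analytic Gaussian-IRF convolution of step and damped-cosine responses.
#
# Both observables follow the same response family: a unit step at t0
# carrying a constant amplitude plus a damped cosine, convolved with a
# Gaussian instrument response of given FWHM. The convolution is done in
# closed form through the scaled complementary error function of complex
# argument, so model values are exact at every requested delay (no grid).

# scaled complementary error function erfcx(z) = exp(z^2) erfc(z) for
# complex z with Re(z) >= 0. Series/erfz for moderate |z|, Laplace
# continued fraction beyond (cancellation-free in both regimes).
erfcx_cplx <- function(z) {
  out <- complex(length(z))
  small <- Mod(z) <= 4
  if (any(small)) {
    zs <- z[small]
    out[small] <- exp(zs^2) * (1 - pracma::erfz(zs))
  }
  if (any(!small)) {
    zl <- z[!small]
    # erfcx(z) = (1/sqrt(pi)) / (z + (1/2)/(z + 1/(z + (3/2)/(z + ...))))
    cf <- complex(length(zl))
    for (m in rev(seq_len(40))) cf <- (m / 2) / (zl + cf)
    out[!small] <- (1 / sqrt(pi)) / (zl + cf)
  }
  out
}

# H(dt) * exp(-k*dt) convolved with a zero-mean Gaussian of s.d. sigma;
# k may be complex (Re k = 1/decay, -Im k = angular frequency).
# Returns complex values; sigma = 0 gives the unconvolved response.
conv_exp_step <- function(dt, k, sigma) {
  if (sigma <= 0) {
    return(ifelse(dt >= 0, exp(-k * dt), 0 + 0i))
  }
  u <- (sigma^2 * k - dt) / (sigma * sqrt(2))
  out <- complex(length(dt))
  pos <- Re(u) >= 0
  if (any(pos)) {
    # exp(sigma^2 k^2/2 - k dt) erfc(u) rewritten via erfcx: the combined
    # exponent collapses to -dt^2/(2 sigma^2), which never overflows.
    out[pos] <- 0.5 * erfcx_cplx(u[pos]) * exp(-dt[pos]^2 / (2 * sigma^2))
  }
  if (any(!pos)) {
    dn <- dt[!pos]
    out[!pos] <- exp(sigma^2 * k^2 / 2 - k * dn) -
      0.5 * erfcx_cplx(-u[!pos]) * exp(-dn^2 / (2 * sigma^2))
  }
  out
}

# Gaussian-smoothed unit step (erf form); sigma = 0 gives H(dt).
smoothed_step <- function(dt, sigma) {
  if (sigma <= 0) as.numeric(dt >= 0) else stats::pnorm(dt / sigma)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Generating parameters of the structural-response trajectories
#'
#' Parameter set for the time courses of the radius of gyration Rg(t) and
#' protein volume Vp(t) after photoexcitation: an instrument-limited step
#' plus a damped cosine for Rg, and a delayed step with exponential
#' relaxation toward a small residual plus a damped cosine for Vp. All
#' times in ps, Rg quantities in Angstrom, Vp quantities in cubic Angstrom.
#'
#' Defaults emulate photolyzed carbonmonoxy-myoglobin: a ~1 A Rg step
#' within 1 ps, a 220 A^3 volume expansion delayed by ~1 ps, relaxation to
#' a ~20 A^3 residual by 100 ps, a 3.6 ps / 6 ps damped oscillation, and a
#' 0.5 ps FWHM Gaussian instrument response. The oscillation amplitudes
#' (0.3 A, 60 A^3) set the oscillation visibly against the step and are
#' freely configurable.
#'
#' @param Rg0,Vp0 ground-state radius of gyration (A) and volume (A^3).
#' @param dRg_step,dVp_step step amplitudes of Rg (A) and Vp (A^3).
#' @param dVp_residual long-delay Vp plateau above ground state, A^3.
#' @param A_osc_rg,A_osc_vp damped-cosine amplitudes for Rg (A) and Vp (A^3).
#' @param vp_delay onset lag of the volume rise after t0, ps.
#' @param T_osc,tau_osc oscillation period and 1/e decay time, ps.
#' @param phi oscillation phase at onset, rad.
#' @param tau_relax decay time of dVp from the step toward the residual, ps.
#' @param t0 nominal time zero, ps.
#' @param irf_fwhm Gaussian instrument-response FWHM, ps (0 disables the
#'   convolution).
#' @return an object of class `"trajectory_params"`.
#' @export
trajectory_params <- function(Rg0 = 17, Vp0 = 23000,
                              dRg_step = 1.0, dVp_step = 220,
                              dVp_residual = 20,
                              A_osc_rg = 0.3, A_osc_vp = 60,
                              vp_delay = 1.0,
                              T_osc = 3.6, tau_osc = 6,
                              phi = 0, tau_relax = 20,
                              t0 = 0, irf_fwhm = 0.5) {
  p <- list(Rg0 = Rg0, Vp0 = Vp0, dRg_step = dRg_step, dVp_step = dVp_step,
            dVp_residual = dVp_residual, A_osc_rg = A_osc_rg,
            A_osc_vp = A_osc_vp, vp_delay = vp_delay, T_osc = T_osc,
            tau_osc = tau_osc, phi = phi, tau_relax = tau_relax, t0 = t0,
            irf_fwhm = irf_fwhm)
  viol <- validate_trajectory_params(p)
  if (length(viol)) stop("invalid trajectory_params: ",
                         paste(viol, collapse = "; "))
  structure(p, class = "trajectory_params")
}

validate_trajectory_params <- function(p) {
  viol <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) viol <<- c(viol, msg)
  chk(p$T_osc > 0, "T_osc must be > 0")
  chk(p$tau_osc > 0, "tau_osc must be > 0")
  chk(p$tau_relax > 0, "tau_relax must be > 0")
  chk(p$irf_fwhm >= 0, "irf_fwhm must be >= 0")
  chk(p$Rg0 > 0, "Rg0 must be > 0")
  chk(p$Vp0 > 0, "Vp0 must be > 0")
  chk(p$vp_delay >= 0, "vp_delay must be >= 0")
  viol
}

#' Structural-parameter trajectories
#'
#' Evaluate the generating model of the radius of gyration and protein
#' volume at pump--probe delays `t`.
#'
#' `rg_trajectory(t)` is
#' \deqn{R_g(t) = R_{g0} + \mathrm{IRF}\ast\left[H(t-t_0)\,(\Delta R_g +
#'   A \cos(2\pi(t-t_0)/T + \phi)\, e^{-(t-t_0)/\tau})\right]}
#' and `vp_trajectory` follows the same family with its step delayed by
#' `vp_delay` and relaxing exponentially (time constant `tau_relax`) from
#' `dVp_step` toward `dVp_residual`. The Gaussian IRF convolution is
#' evaluated in closed form.
#'
#' @param t delays in ps (vectorised).
#' @param p a [trajectory_params()].
#' @return Rg in Angstrom / Vp in cubic Angstrom at each `t`.
#' @export
rg_trajectory <- function(t, p) {
  stopifnot(inherits(p, "trajectory_params"))
  p$Rg0 + kinetic_model(t, A = p$dRg_step, A_osc = p$A_osc_rg,
                        T_osc = p$T_osc, tau_osc = p$tau_osc,
                        phi = p$phi, t0 = p$t0, irf_fwhm = p$irf_fwhm)
}

#' @rdname rg_trajectory
#' @export
vp_trajectory <- function(t, p) {
  stopifnot(inherits(p, "trajectory_params"))
  sigma <- fwhm_to_sigma(p$irf_fwhm)
  dt <- t - p$t0 - p$vp_delay
  k_osc <- 1 / p$tau_osc - 2i * pi / p$T_osc
  p$Vp0 +
    p$dVp_residual * smoothed_step(dt, sigma) +
    (p$dVp_step - p$dVp_residual) *
      Re(conv_exp_step(dt, complex(real = 1 / p$tau_relax), sigma)) +
    p$A_osc_vp * Re(exp(1i * p$phi) * conv_exp_step(dt, k_osc, sigma))
}
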