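#' Damped-oscillation kinetic model with Gaussian IRF
#'
#' The phenomenological response of a structural observable after an
#' impulsive perturbation: a step of amplitude `A` at `t0` plus a damped
#' cosine of amplitude `A_osc`, period `T_osc` and decay time `tau_osc`,
#' convolved with a Gaussian instrument response of FWHM `irf_fwhm`.
#' The value tends to 0 for `t` well before `t0` and to `A` once the
#' oscillation has damped out. The baseline is not included; add the
#' ground-state value for an absolute trajectory.
#'
#' @param t delays, ps (vectorised).
#' @param A step amplitude (observable units).
#' @param A_osc oscillation amplitude (observable units).
#' @param T_osc oscillation period, ps.
#' @param tau_osc oscillation 1/e decay time, ps.
#' @param phi phase at t0, rad.
#' @param t0 time zero, ps.
#' @param irf_fwhm Gaussian IRF FWHM, ps (0 = no convolution).
#' @param include_step if `FALSE`, only the damped-cosine part is returned
#'   (oscillation about an equilibrium already subtracted from the data).
#' @return model values at `t`.
#' @export
kinetic_model <- function(t, A, A_osc, T_osc, tau_osc, phi = 0, t0 = 0,
                          irf_fwhm = 0.5, include_step = TRUE) {
  stopifnot(T_osc > 0, tau_osc > 0, irf_fwhm >= 0)
  sigma <- fwhm_to_sigma(irf_fwhm)
  dt <- t - t0
  k <- 1 / tau_osc - 2i * pi / T_osc
  osc <- A_osc * Re(exp(1i * phi) * conv_exp_step(dt, k, sigma))
  if (include_step) A * smoothed_step(dt, sigma) + osc else osc
}

.kin_par_names <- c("A", "A_osc", "T_osc", "tau_osc", "phi", "t0")

.kin_residuals <- function(par, fixed, series, irf_fwhm, include_step,
                           T_min = 0) {
  p <- c(as.list(par), as.list(fixed))
  if (p$T_osc <= 0 || p$T_osc < T_min || p$tau_osc <= 0) {
    return(rep(1e6, length(series$delay)))
  }
  m <- kinetic_model(series$delay, A = p$A, A_osc = p$A_osc,
                     T_osc = p$T_osc, tau_osc = p$tau_osc, phi = p$phi,
                     t0 = p$t0, irf_fwhm = irf_fwhm,
                     include_step = include_step)
  (m - series$value) / series$error
}

# forward-difference Jacobian of a residual function at the optimum
.num_jacobian <- function(fn, par) {
  r0 <- fn(par)
  J <- matrix(0, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- max(1e-7, abs(par[j]) * 1e-7)
    pj <- par; pj[j] <- pj[j] + h
    J[, j] <- (fn(pj) - r0) / h
  }
  J
}

.as_delay_series <- function(series) {
  if (inherits(series, "delay_series")) series <- as.data.frame(series)
  series <- as.data.frame(series)
  need <- c("delay", "value", "error")
  if (!all(need %in% names(series))) {
    stop("series must have columns delay, value, error")
  }
  if (any(series$error <= 0)) stop("series errors must be > 0")
  series[order(series$delay), need]
}

#' Fit the damped-oscillation kinetic model to a delay series
#'
#' Weighted least-squares fit of [kinetic_model()] to a series of
#' (delay, value, 1-s.d. error) points, e.g. a Delta-Rg(t) or Delta-Vp(t)
#' series from [fit_series()]. Damped-cosine fits are multimodal, so the
#' optimiser is multi-started over a grid of trial periods and phases and
#' the best reduced chi-square solution is kept. Parameter 1-s.d. errors
#' come from the unscaled covariance \eqn{(J^T W J)^{-1}} at the optimum.
#'
#' The fitted phase is reported in (-pi, pi] with a non-negative
#' oscillation amplitude. A fit whose period uncertainty exceeds half the
#' period, or whose oscillation amplitude is not distinguishable from zero
#' at 2 s.d., is flagged `period_resolved = FALSE`.
#'
#' @param series data frame (or `delay_series`) with columns `delay`,
#'   `value`, `error`.
#' @param irf_fwhm Gaussian IRF FWHM in ps, fixed during the fit
#'   (default 0.5).
#' @param fixed named numeric vector of parameters to hold fixed, e.g.
#'   `c(t0 = 0)` or `c(T_osc = 3.6)`.
#' @param include_step fit the step plus oscillation (default) or the
#'   oscillation only.
#' @param period_grid trial periods for the multi-start, ps; periods below
#'   twice the finest delay spacing are sub-Nyquist for the series and are
#'   excluded from the final solution.
#' @param phase_grid trial phases for the multi-start, rad.
#' @param init optional named vector overriding the default initial values
#'   of the non-gridded parameters.
#' @return an object of class `"kinetic_fit"` with `coefficients`,
#'   `se`, `cov`, `chi2red`, `period_resolved`, the data and the settings.
#' @export
fit_kinetics <- function(series, irf_fwhm = 0.5, fixed = NULL,
                         include_step = TRUE,
                         period_grid = seq(1, 8, by = 0.25),
                         phase_grid = c(0, pi / 2, -pi / 2, pi),
                         init = NULL) {
  series <- .as_delay_series(series)
  if (nrow(series) < 10) stop("need at least 10 points to fit kinetics")
  span <- diff(range(series$delay))
  if (span < min(period_grid)) stop("series span shorter than one period")
  # periods the series cannot resolve (below twice the finest spacing)
  # are aliases, not measurements
  T_min <- 2 * min(diff(sort(unique(series$delay))))

  step0 <- mean(series$value[series$delay > stats::median(series$delay)])
  osc0 <- stats::sd(series$value - step0 * (series$delay > 0))
  defaults <- c(A = if (include_step) step0 else 0,
                A_osc = max(osc0, 1e-12), T_osc = NA, tau_osc = span / 4,
                phi = NA, t0 = 0)
  if (!is.null(init)) defaults[names(init)] <- init
  fixed <- if (is.null(fixed)) numeric(0) else fixed
  if (!include_step && !("A" %in% names(fixed))) fixed <- c(fixed, A = 0)
  free_names <- setdiff(.kin_par_names, names(fixed))

  if ("T_osc" %in% names(fixed)) period_grid <- fixed[["T_osc"]]
  if ("phi" %in% names(fixed)) phase_grid <- fixed[["phi"]]
  starts <- expand.grid(T_osc = period_grid, phi = phase_grid)

  # rank all starts by their initial deviance; run the optimiser only from
  # the most promising ones (the surface is multimodal in period/phase but
  # the deviance at the start already separates the basins)
  start_dev <- vapply(seq_len(nrow(starts)), function(i) {
    par0 <- defaults
    par0["T_osc"] <- starts$T_osc[i]
    par0["phi"] <- starts$phi[i]
    sum(.kin_residuals(par0[free_names], fixed, series, irf_fwhm,
                       include_step, T_min)^2)
  }, numeric(1))
  n_run <- min(nrow(starts), 8L)
  run_idx <- order(start_dev)[seq_len(n_run)]

  best <- NULL
  for (i in run_idx) {
    par0 <- defaults
    par0["T_osc"] <- starts$T_osc[i]
    par0["phi"] <- starts$phi[i]
    par0 <- par0[free_names]
    # box constraints at the identifiability limits: periods below the
    # Nyquist spacing or beyond the span, and decay times beyond the span,
    # are not measurable from this series
    lower <- c(A = -Inf, A_osc = -Inf, T_osc = T_min, tau_osc = 1e-3,
               phi = -Inf, t0 = -Inf)[free_names]
    upper <- c(A = Inf, A_osc = Inf, T_osc = span, tau_osc = span,
               phi = Inf, t0 = Inf)[free_names]
    par0 <- pmin(pmax(par0, lower), upper)
    ans <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(par = par0, fn = .kin_residuals, fixed = fixed,
                         series = series, irf_fwhm = irf_fwhm,
                         include_step = include_step, T_min = T_min,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 60, ptol = 1e-9, ftol = 1e-9))),
      error = function(e) NULL)
    if (is.null(ans)) next
    dev <- sum(ans$fvec^2)
    if (is.null(best) || dev < best$dev - 1e-12) {
      best <- list(fit = ans, dev = dev)
    }
  }
  if (is.null(best)) stop("kinetic fit failed to converge from any start")

  # polish the winning start at tight tolerance
  polish <- tryCatch(suppressWarnings(
    minpack.lm::nls.lm(par = best$fit$par, fn = .kin_residuals,
                       fixed = fixed, series = series,
                       irf_fwhm = irf_fwhm, include_step = include_step,
                       T_min = T_min, lower = lower, upper = upper,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 300, ptol = 1e-13, ftol = 1e-13))),
    error = function(e) NULL)
  if (!is.null(polish) && sum(polish$fvec^2) <= best$dev + 1e-9) {
    best$fit <- polish
  }

  par <- best$fit$par
  # canonical form: positive oscillation amplitude, phase in (-pi, pi]
  if (!is.na(par["A_osc"]) && "A_osc" %in% names(par) && par["A_osc"] < 0) {
    par["A_osc"] <- -par["A_osc"]
    if ("phi" %in% names(par)) par["phi"] <- par["phi"] + pi
  }
  if ("phi" %in% names(par)) {
    par["phi"] <- ((par["phi"] + pi) %% (2 * pi)) - pi
    if (par["phi"] == -pi) par["phi"] <- pi
  }
  if ("T_osc" %in% names(par)) par["T_osc"] <- abs(par["T_osc"])

  fn <- function(p) .kin_residuals(p, fixed, series, irf_fwhm,
                                   include_step, T_min)
  J <- .num_jacobian(fn, par)
  JtJ <- crossprod(J)
  cov <- tryCatch(solve(JtJ), error = function(e) NULL)
  degenerate <- is.null(cov) || any(!is.finite(diag(cov))) ||
    any(diag(cov) < 0)
  se <- if (degenerate) rep(NA_real_, length(par)) else sqrt(diag(cov))
  names(se) <- names(par)

  n <- nrow(series)
  chi2red <- sum(fn(par)^2) / max(n - length(par), 1)
  coefs <- c(par, fixed[setdiff(names(fixed), names(par))])
  coefs <- coefs[intersect(.kin_par_names, names(coefs))]

  # a resolved period needs a significant amplitude, a period known to
  # better than half itself, and an envelope that survives at least half
  # a period (a faster-dying blip cannot carry a period)
  period_resolved <- !degenerate &&
    !is.na(se["T_osc"]) && se["T_osc"] < coefs["T_osc"] / 2 &&
    ("A_osc" %in% names(se)) && coefs["A_osc"] > 2 * se["A_osc"] &&
    coefs["tau_osc"] > coefs["T_osc"] / 2
  tau_capped <- !("tau_osc" %in% names(fixed)) &&
    coefs[["tau_osc"]] >= 0.95 * span

  structure(list(coefficients = coefs, se = se, cov = cov,
                 chi2red = chi2red, n = n, df = n - length(par),
                 irf_fwhm = irf_fwhm, include_step = include_step,
                 fixed = fixed, period_resolved = isTRUE(period_resolved),
                 tau_capped = tau_capped,
                 degenerate = degenerate, series = series),
            class = "kinetic_fit")
}

#' @export
coef.kinetic_fit <- function(object, ...) object$coefficients

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Damped-oscillation kinetic fit\n")
  cat(sprintf("  %d points, chi2_red = %.3g, IRF FWHM = %g ps\n",
              x$n, x$chi2red, x$irf_fwhm))
  cf <- x$coefficients
  se <- x$se[names(cf)]
  for (nm in names(cf)) {
    if (nm %in% names(x$fixed)) {
      cat(sprintf("  %-8s %10.4g   (fixed)\n", nm, cf[nm]))
    } else {
      cat(sprintf("  %-8s %10.4g +/- %.3g\n", nm, cf[nm], se[nm]))
    }
  }
  if (!x$period_resolved) cat("  note: oscillation period not resolved\n")
  if (isTRUE(x$tau_capped)) {
    cat("  note: decay time at the series-span bound (unresolved)\n")
  }
  invisible(x)
}

#' @export
summary.kinetic_fit <- function(object, ...) {
  cf <- object$coefficients
  out <- data.frame(estimate = cf, se = object$se[names(cf)],
                    fixed = names(cf) %in% names(object$fixed))
  attr(out, "chi2red") <- object$chi2red
  out
}

#' @export
predict.kinetic_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$series$delay else {
    if (is.list(newdata)) newdata$delay else newdata
  }
  cf <- object$coefficients
  kinetic_model(t, A = cf[["A"]], A_osc = cf[["A_osc"]],
                T_osc = cf[["T_osc"]], tau_osc = cf[["tau_osc"]],
                phi = cf[["phi"]], t0 = cf[["t0"]],
                irf_fwhm = object$irf_fwhm,
                include_step = object$include_step)
}

#' @export
residuals.kinetic_fit <- function(object, ...) {
  object$series$value - predict(object)
}

#' @export
plot.kinetic_fit <- function(x, ...) {
  s <- x$series
  plot(s$delay, s$value, pch = 16, xlab = "delay (ps)",
       ylab = "observable", ...)
  graphics::arrows(s$delay, s$value - s$error, s$delay, s$value + s$error,
                   angle = 90, code = 3, length = 0.02, col = "grey50")
  tt <- seq(min(s$delay), max(s$delay), length.out = 500)
  graphics::lines(tt, predict(x, tt), col = "red", lwd = 2)
  invisible(x)
}

#' Reduced chi-square profile over trial oscillation periods
#'
#' Robustness diagnostic for [fit_kinetics()]: for each trial period the
#' model is refitted with the period held fixed and the best reduced
#' chi-square recorded. The global minimum of the profile coincides with
#' the free-fit period.
#'
#' @inheritParams fit_kinetics
#' @param T_grid trial periods, ps; must lie within
#'   `[2 * median spacing, span / 2]` of the series.
#' @return data frame of class `"period_scan"` with columns `T_osc` and
#'   `chi2red`.
#' @export
period_scan <- function(series, T_grid, irf_fwhm = 0.5, fixed = NULL,
                        include_step = TRUE) {
  series <- .as_delay_series(series)
  if (length(T_grid) == 0) stop("empty period grid")
  span <- diff(range(series$delay))
  lo <- 2 * stats::median(diff(sort(series$delay)))
  if (any(T_grid < lo) || any(T_grid > span / 2)) {
    stop("T_grid must lie within [2 * median spacing, span/2] = [",
         signif(lo, 3), ", ", signif(span / 2, 3), "] ps")
  }
  chi2 <- vapply(T_grid, function(Ti) {
    f <- tryCatch(
      fit_kinetics(series, irf_fwhm = irf_fwhm,
                   fixed = c(fixed, T_osc = Ti),
                   include_step = include_step,
                   period_grid = Ti),
      error = function(e) NULL)
    if (is.null(f)) NA_real_ else f$chi2red
  }, numeric(1))
  structure(data.frame(T_osc = T_grid, chi2red = chi2)[order(T_grid), ],
            class = c("period_scan", "data.frame"))
}

#' @export
plot.period_scan <- function(x, ...) {
  plot(x$T_osc, x$chi2red, type = "b", pch = 16,
       xlab = "trial period (ps)", ylab = expression(chi[red]^2), ...)
  invisible(x)
}
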