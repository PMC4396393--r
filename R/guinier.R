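#' Constants of the constant-electron-count Guinier model
#'
#' In the Guinier regime the scattering of a dilute protein solution is
#' \deqn{I(q) = (\Delta\rho V_p)^2 \exp(-q^2 R_g^2 / 3)}
#' with contrast \eqn{\Delta\rho = \rho_p - \rho_b}. A conformational
#' change may alter \eqn{V_p} and \eqn{R_g} but not the total electron
#' count \eqn{N_e = \rho_p V_p}, which is therefore held fixed, so the
#' prefactor depends on the volume only through \eqn{(N_e - \rho_b V_p)^2}.
#'
#' @param Ne total protein electron count (default 9900, myoglobin).
#' @param rho_b buffer electron density, electrons per cubic Angstrom
#'   (default 0.34).
#' @param Rg0 ground-state radius of gyration, Angstrom (default 17).
#' @param Vp0 ground-state protein volume, cubic Angstrom (default 23000;
#'   not measurable from difference data alone, see the methods vignette).
#' @return an object of class `"guinier_constants"`.
#' @export
guinier_constants <- function(Ne = 9900, rho_b = 0.34, Rg0 = 17,
                              Vp0 = 23000) {
  stopifnot(Ne > 0, rho_b > 0, Rg0 > 0, Vp0 > 0)
  if (Ne / Vp0 <= rho_b) {
    stop("Ne/Vp0 must exceed rho_b (protein contrast must be positive)")
  }
  structure(list(Ne = Ne, rho_b = rho_b, Rg0 = Rg0, Vp0 = Vp0),
            class = "guinier_constants")
}

#' Guinier intensity at constant electron count
#'
#' @param q momentum transfer, inverse Angstrom (vectorised).
#' @param Rg radius of gyration, Angstrom.
#' @param Vp protein volume, cubic Angstrom.
#' @param const a [guinier_constants()].
#' @return intensity in squared electrons.
#' @export
guinier_intensity <- function(q, Rg, Vp, const = guinier_constants()) {
  stopifnot(inherits(const, "guinier_constants"))
  if (Vp <= 0) stop("Vp must be > 0")
  if (Rg <= 0) stop("Rg must be > 0")
  drho_Vp <- const$Ne - const$rho_b * Vp  # (rho_p - rho_b) * Vp at fixed Ne
  if (drho_Vp <= 0) stop("contrast vanished: Ne - rho_b * Vp <= 0")
  drho_Vp^2 * exp(-q^2 * Rg^2 / 3)
}

#' Difference-Guinier model
#'
#' Laser-on minus reference Guinier intensity for a change
#' (`dRg`, `dVp`) of the structural parameters at fixed electron count:
#' \deqn{\Delta I(q) = \alpha [ I(q; R_{g0}+\Delta R_g, V_{p0}+\Delta V_p)
#'   - I(q; R_{g0}, V_{p0}) ]}
#' At q = 0 the sign of \eqn{\Delta I} follows the sign of
#' \eqn{(N_e-\rho_b(V_{p0}+\Delta V_p))^2 - (N_e-\rho_b V_{p0})^2}: an
#' expansion lowers the forward scattering.
#'
#' @inheritParams guinier_intensity
#' @param dRg radius-of-gyration change, Angstrom.
#' @param dVp volume change, cubic Angstrom.
#' @param alpha global amplitude (photoexcited fraction), default 1.
#' @return difference intensity in squared electrons.
#' @export
diff_guinier_model <- function(q, dRg, dVp, alpha = 1,
                               const = guinier_constants()) {
  alpha * (guinier_intensity(q, const$Rg0 + dRg, const$Vp0 + dVp, const) -
             guinier_intensity(q, const$Rg0, const$Vp0, const))
}

#' Fit the difference-Guinier model to one difference pattern
#'
#' Weighted least squares of [diff_guinier_model()] over a low-q window,
#' with free parameters `dRg` and `dVp` (and optionally the global
#' amplitude `alpha`). 1-s.d. errors are taken from the unscaled
#' covariance \eqn{(J^T W J)^{-1}} at the optimum; with correctly stated
#' per-point uncertainties these are calibrated against replicate scatter.
#'
#' Difference patterns produced by [reduce_run()] are on the normalized
#' scale (window mean of the absolute pattern = 1); the recorded
#' normalization factor (`meta$norm_scale`) is used to restore the data to
#' the model's counts scale, so that `alpha` can stay fixed at 1. Set
#' `free_alpha = TRUE` for data of unknown absolute scale (note `alpha`
#' then trades against `dVp`).
#'
#' @param pattern a [pattern1d()] difference pattern (fields `q`, `I` =
#'   Delta-I, `sigma`).
#' @param q_range fit window in inverse Angstrom (default `c(0.02, 0.08)`,
#'   within Guinier validity `q * Rg <~ 1.4`).
#' @param const a [guinier_constants()].
#' @param init initial `c(dRg, dVp)` (default `c(0, 0)`).
#' @param free_alpha also fit the global amplitude.
#' @param scale counts-per-normalized-unit factor applied to `I` and
#'   `sigma` before fitting; defaults to `pattern$meta$norm_scale` when
#'   present, else 1.
#' @param unit_weights fit with uniform weights instead of `1/sigma^2`;
#'   required for noiseless patterns whose stated uncertainties are zero
#'   (the reported parameter errors then have no statistical meaning).
#' @return an object of class `"guinier_fit"`.
#' @export
fit_difference <- function(pattern, q_range = c(0.02, 0.08),
                           const = guinier_constants(),
                           init = c(dRg = 0, dVp = 0),
                           free_alpha = FALSE, scale = NULL,
                           unit_weights = FALSE) {
  stopifnot(inherits(pattern, "pattern1d"))
  if (is.null(scale)) {
    scale <- if (!is.null(pattern$meta$norm_scale)) {
      pattern$meta$norm_scale
    } else 1
  }
  sel <- pattern$q >= q_range[1] & pattern$q <= q_range[2]
  if (sum(sel) < 8) stop("need at least 8 points in q_range")
  q <- pattern$q[sel]
  dI <- pattern$I[sel] * scale
  sig <- pattern$sigma[sel] * scale
  if (unit_weights) sig <- rep(1, length(q))
  if (any(sig <= 0)) stop("sigma must be > 0 over the fit range")

  par0 <- c(dRg = unname(init[1]), dVp = unname(init[2]))
  if (free_alpha) par0 <- c(par0, alpha = 1)
  resid_fn <- function(par) {
    alpha <- if (free_alpha) par[["alpha"]] else 1
    m <- tryCatch(
      diff_guinier_model(q, par[["dRg"]], par[["dVp"]], alpha, const),
      error = function(e) NULL)
    if (is.null(m)) return(rep(1e8, length(q)))
    (m - dI) / sig
  }
  ans <- minpack.lm::nls.lm(
    par = par0, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-12,
                                         ftol = 1e-14))
  converged <- ans$info %in% 1:4
  if (!converged) {
    warning("difference-Guinier fit did not converge: ", ans$message)
  }
  par <- ans$par
  J <- .num_jacobian(resid_fn, par)
  cov <- tryCatch(solve(crossprod(J)), error = function(e) NULL)
  degenerate <- is.null(cov) || any(!is.finite(diag(cov))) ||
    any(diag(cov) < 0)
  se <- if (degenerate) rep(NA_real_, length(par)) else sqrt(diag(cov))
  names(se) <- names(par)
  n <- length(q)
  chi2red <- sum(resid_fn(par)^2) / max(n - length(par), 1)
  alpha_hat <- if (free_alpha) par[["alpha"]] else 1

  structure(list(coefficients = par, se = se, cov = cov,
                 alpha = alpha_hat, chi2red = chi2red,
                 q_range = q_range, n = n, scale = scale,
                 const = const, converged = converged,
                 degenerate = degenerate,
                 delay = if (!is.null(pattern$meta$delay))
                   pattern$meta$delay else NA_real_,
                 data = list(q = q, dI = dI, sigma = sig)),
            class = "guinier_fit")
}

#' @export
coef.guinier_fit <- function(object, ...) object$coefficients

#' @export
print.guinier_fit <- function(x, ...) {
  cat("Difference-Guinier fit")
  if (!is.na(x$delay)) cat(sprintf(" (delay %g ps)", x$delay))
  cat("\n")
  cat(sprintf("  dRg  = %8.4g +/- %.3g A\n",
              x$coefficients[["dRg"]], x$se[["dRg"]]))
  cat(sprintf("  dVp  = %8.4g +/- %.3g A^3\n",
              x$coefficients[["dVp"]], x$se[["dVp"]]))
  if ("alpha" %in% names(x$coefficients)) {
    cat(sprintf("  alpha = %.4g +/- %.3g\n",
                x$coefficients[["alpha"]], x$se[["alpha"]]))
  }
  cat(sprintf("  chi2_red = %.3g over %d points, q in [%g, %g] 1/A\n",
              x$chi2red, x$n, x$q_range[1], x$q_range[2]))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  if (x$degenerate) cat("  WARNING: degenerate covariance\n")
  invisible(x)
}

#' @export
predict.guinier_fit <- function(object, newdata = NULL, ...) {
  q <- if (is.null(newdata)) object$data$q else {
    if (is.list(newdata)) newdata$q else newdata
  }
  diff_guinier_model(q, object$coefficients[["dRg"]],
                     object$coefficients[["dVp"]], object$alpha,
                     object$const)
}

#' @export
residuals.guinier_fit <- function(object, ...) {
  object$data$dI - predict(object)
}

#' @export
plot.guinier_fit <- function(x, ...) {
  plot(x$data$q, x$data$dI, pch = 16, xlab = "q (1/A)",
       ylab = expression(Delta * I), ...)
  graphics::arrows(x$data$q, x$data$dI - x$data$sigma, x$data$q,
                   x$data$dI + x$data$sigma, angle = 90, code = 3,
                   length = 0.02, col = "grey50")
  qq <- seq(min(x$data$q), max(x$data$q), length.out = 300)
  graphics::lines(qq, predict(x, qq), col = "red", lwd = 2)
  invisible(x)
}

#' Fit a series of per-delay difference patterns
#'
#' Applies [fit_difference()] to each pattern and collects the
#' Delta-Rg(t) and Delta-Vp(t) series in delay order. Per-delay failures
#' are recorded (`ok = FALSE`, coefficients `NA`), never silently dropped.
#'
#' @param patterns list of [pattern1d()] difference patterns with
#'   `meta$delay` set.
#' @param ... passed on to [fit_difference()].
#' @return an object of class `"guinier_series"`: a data frame with
#'   columns `delay`, `dRg`, `dRg_se`, `dVp`, `dVp_se`, `chi2red`, `ok`,
#'   plus the individual fits in `attr(, "fits")`.
#' @export
fit_series <- function(patterns, ...) {
  if (length(patterns) == 0) stop("no patterns to fit")
  fits <- lapply(patterns, function(p) {
    tryCatch(fit_difference(p, ...), error = function(e) e)
  })
  rows <- lapply(seq_along(patterns), function(i) {
    f <- fits[[i]]
    d <- if (!is.null(patterns[[i]]$meta$delay)) {
      patterns[[i]]$meta$delay
    } else NA_real_
    if (inherits(f, "guinier_fit")) {
      data.frame(delay = d, dRg = f$coefficients[["dRg"]],
                 dRg_se = f$se[["dRg"]], dVp = f$coefficients[["dVp"]],
                 dVp_se = f$se[["dVp"]], chi2red = f$chi2red,
                 ok = f$converged)
    } else {
      data.frame(delay = d, dRg = NA_real_, dRg_se = NA_real_,
                 dVp = NA_real_, dVp_se = NA_real_, chi2red = NA_real_,
                 ok = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$delay), ]
  rownames(out) <- NULL
  structure(out, fits = fits, class = c("guinier_series", "data.frame"))
}

#' Extract one observable of a fitted series as a delay series
#'
#' @param series a `"guinier_series"` from [fit_series()].
#' @param observable `"dRg"` or `"dVp"`.
#' @return a data frame of class `"delay_series"` with columns `delay`,
#'   `value`, `error` (failed delays dropped), ready for [fit_kinetics()].
#' @export
delay_series <- function(series, observable = c("dRg", "dVp")) {
  observable <- match.arg(observable)
  stopifnot(inherits(series, "guinier_series"))
  df <- as.data.frame(series)
  df <- df[df$ok & is.finite(df[[observable]]), ]
  structure(data.frame(delay = df$delay, value = df[[observable]],
                       error = df[[paste0(observable, "_se")]]),
            observable = observable,
            class = c("delay_series", "data.frame"))
}

#' @export
plot.guinier_series <- function(x, observable = "dRg", ...) {
  s <- delay_series(x, observable)
  plot(s$delay, s$value, pch = 16, xlab = "delay (ps)", ylab = observable,
       ...)
  graphics::arrows(s$delay, s$value - s$error, s$delay, s$value + s$error,
                   angle = 90, code = 3, length = 0.02, col = "grey50")
  invisible(x)
}
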