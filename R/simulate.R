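#' Pump--probe delay schedule
#'
#' The acquisition schedule of a pump--probe run: the list of pump--probe
#' delays, the number of repetitions per delay, and the interleaving of
#' reference frames (probe long before pump) every `reference_interval`
#' laser-on frames. Defaults follow the myoglobin experiment: every 0.5 ps
#' between -3 and 10 ps, every 5 ps between 10 and 50 ps, every 50 ps
#' beyond (here up to 100 ps); references at -100 ps every 7 frames;
#' 50 repetitions per delay.
#'
#' @param delays pump--probe delays in ps, sorted.
#' @param repetitions frames per delay (>= 1).
#' @param reference_delay delay of the reference frames, ps.
#' @param reference_interval a reference frame is inserted after every this
#'   many laser-on frames.
#' @return an object of class `"delay_schedule"`.
#' @export
delay_schedule <- function(delays = c(seq(-3, 10, by = 0.5),
                                      seq(15, 50, by = 5), 100),
                           repetitions = 50,
                           reference_delay = -100,
                           reference_interval = 7) {
  delays <- sort(as.numeric(delays))
  stopifnot(length(delays) >= 1, repetitions >= 1, reference_interval >= 1)
  structure(list(delays = delays, repetitions = as.integer(repetitions),
                 reference_delay = reference_delay,
                 reference_interval = as.integer(reference_interval)),
            class = "delay_schedule")
}

#' Shot-noise and corrupted-shot model
#'
#' Per-frame statistical model of the generator: each q-bin of a frame is
#' drawn as model value times `(1 + N(0, sigma_rel))`, with the per-bin
#' 1-s.d. uncertainty recorded as `sigma_rel` times the model value. A
#' fraction of the repetitions at every delay is replaced by corrupted
#' shots: the frame is multiplied by a smooth low-order polynomial
#' distortion of relative amplitude `outlier_scale`, emulating
#' beam-pointing and capillary artifacts. Ground-truth corruption labels
#' are kept in the run manifest for validation.
#'
#' @param sigma_rel relative per-point Gaussian noise (default 0.001,
#'   i.e. 0.1% per bin on a 360-shot accumulation).
#' @param outlier_fraction fraction of repetitions per delay replaced by
#'   corrupted shots, in `[0, 1)` (default 0.2).
#' @param outlier_scale relative amplitude of the smooth distortion on
#'   corrupted shots (default 0.02).
#' @return an object of class `"noise_model"`.
#' @export
noise_model <- function(sigma_rel = 0.001, outlier_fraction = 0.2,
                        outlier_scale = 0.02) {
  stopifnot(sigma_rel >= 0, outlier_fraction >= 0, outlier_fraction < 1,
            outlier_scale >= 0)
  structure(list(sigma_rel = sigma_rel,
                 outlier_fraction = outlier_fraction,
                 outlier_scale = outlier_scale),
            class = "noise_model")
}

#' Solvent/WAXS background curve
#'
#' Smooth, time-independent background standing in for the solvent and
#' wide-angle scattering: a broad water-like peak centered near 2 inverse
#' Angstrom plus a pedestal, strictly positive over the 1.3--1.5
#' normalization window. Units match the Guinier term (squared electrons).
#'
#' @param q momentum transfer grid, inverse Angstrom.
#' @param amplitude peak amplitude (default 5e6).
#' @param center,width peak center and Gaussian width, inverse Angstrom.
#' @param pedestal constant offset (default 1e5).
#' @return background intensity at `q`.
#' @export
default_background <- function(q, amplitude = 5e6, center = 2.0,
                               width = 0.5, pedestal = 1e5) {
  amplitude * exp(-(q - center)^2 / (2 * width^2)) + pedestal
}

#' Absolute scattering pattern from structural parameters
#'
#' Model curve of one frame: the constant-electron-count Guinier term
#' plus the time-independent background,
#' \eqn{I(q) = (\Delta\rho V_p)^2 e^{-q^2 R_g^2/3} + B(q)}.
#'
#' @param q_grid momentum-transfer grid, inverse Angstrom.
#' @param Rg radius of gyration, Angstrom.
#' @param Vp protein volume, cubic Angstrom (> 0).
#' @param const a [guinier_constants()] supplying `Ne` and `rho_b`.
#' @param background function of `q` returning the background curve
#'   (default [default_background()]); use `function(q) 0 * q` to disable.
#' @return a [pattern1d()] with `sigma = 0`.
#' @export
absolute_pattern <- function(q_grid, Rg, Vp, const = guinier_constants(),
                             background = default_background) {
  I <- guinier_intensity(q_grid, Rg, Vp, const) + background(q_grid)
  pattern1d(q_grid, I)
}

# smooth multiplicative distortion for corrupted shots: a random cubic in
# scaled q, normalized to unit maximum amplitude
.corruption_curve <- function(q, scale) {
  u <- 2 * (q - min(q)) / (max(q) - min(q)) - 1
  co <- stats::rnorm(4)
  p <- co[1] + co[2] * u + co[3] * u^2 + co[4] * u^3
  1 + scale * p / max(abs(p))
}

#' Simulate a full pump--probe scattering run
#'
#' Generates the frame stream of a pump--probe experiment: for each
#' scheduled delay, `repetitions` laser-on frames whose model curve is the
#' Guinier-plus-background pattern evaluated at `rg_trajectory(delay)` and
#' `vp_trajectory(delay)`, with an interleaved reference frame (at the
#' reference delay) after every `reference_interval` laser-on frames.
#' Noise and corrupted shots follow the [noise_model()]; at every delay
#' exactly `round(outlier_fraction * repetitions)` repetitions are
#' corrupted, and the ground-truth labels are kept in the manifest.
#' Fully reproducible from `seed`.
#'
#' @param schedule a [delay_schedule()].
#' @param params a [trajectory_params()].
#' @param noise a [noise_model()].
#' @param q_grid momentum-transfer grid (default 0.01--2.5 by 0.0025).
#' @param const a [guinier_constants()].
#' @param background background function, see [absolute_pattern()].
#' @param seed integer RNG seed.
#' @return an object of class `"xss_run"`: list with the common `q` grid,
#'   intensity and sigma matrices (frames in rows), and a `manifest` data
#'   frame (`frame`, `delay`, `is_reference`, `corrupted`).
#' @export
simulate_run <- function(schedule = delay_schedule(),
                         params = trajectory_params(),
                         noise = noise_model(),
                         q_grid = seq(0.01, 2.5, by = 0.0025),
                         const = guinier_constants(),
                         background = default_background,
                         seed = 1) {
  stopifnot(inherits(schedule, "delay_schedule"),
            inherits(params, "trajectory_params"),
            inherits(noise, "noise_model"))
  if (length(schedule$delays) == 0) stop("empty delay schedule")
  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(seed)

  ref_curve <- absolute_pattern(q_grid,
                                rg_trajectory(schedule$reference_delay,
                                              params),
                                vp_trajectory(schedule$reference_delay,
                                              params),
                                const, background)$I

  # build the acquisition order: delay-major, one reference inserted after
  # every reference_interval laser-on frames (and one leading reference)
  on_delays <- rep(schedule$delays, each = schedule$repetitions)
  stream_delay <- numeric(0)
  stream_ref <- logical(0)
  since_ref <- schedule$reference_interval  # force a leading reference
  for (d in on_delays) {
    if (since_ref >= schedule$reference_interval) {
      stream_delay <- c(stream_delay, schedule$reference_delay)
      stream_ref <- c(stream_ref, TRUE)
      since_ref <- 0
    }
    stream_delay <- c(stream_delay, d)
    stream_ref <- c(stream_ref, FALSE)
    since_ref <- since_ref + 1
  }
  nframes <- length(stream_delay)

  # corruption labels: exact count per delay among laser-on frames
  corrupted <- logical(nframes)
  n_corr <- round(noise$outlier_fraction * schedule$repetitions)
  for (d in schedule$delays) {
    idx <- which(!stream_ref & stream_delay == d)
    if (n_corr > 0) {
      corrupted[sample(idx, n_corr)] <- TRUE
    }
  }

  model_I <- matrix(0, nframes, length(q_grid))
  for (d in unique(stream_delay)) {
    curve <- if (d == schedule$reference_delay) ref_curve else {
      absolute_pattern(q_grid, rg_trajectory(d, params),
                       vp_trajectory(d, params), const, background)$I
    }
    model_I[stream_delay == d, ] <- matrix(curve,
                                           sum(stream_delay == d),
                                           length(q_grid), byrow = TRUE)
  }

  I <- model_I
  if (noise$sigma_rel > 0) {
    I <- I * (1 + matrix(stats::rnorm(length(I), 0, noise$sigma_rel),
                         nrow(I), ncol(I)))
  }
  for (i in which(corrupted)) {
    I[i, ] <- I[i, ] * .corruption_curve(q_grid, noise$outlier_scale)
  }
  sigma <- noise$sigma_rel * model_I

  structure(list(q = q_grid, I = I, sigma = sigma,
                 manifest = data.frame(frame = seq_len(nframes),
                                       delay = stream_delay,
                                       is_reference = stream_ref,
                                       corrupted = corrupted),
                 schedule = schedule, params = params, noise = noise,
                 const = const, seed = seed),
            class = "xss_run")
}

#' @export
print.xss_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("Synthetic pump-probe run: %d frames (%d laser-on, ",
                     "%d reference), %d q-bins\n"),
              nrow(m), sum(!m$is_reference), sum(m$is_reference),
              length(x$q)))
  cat(sprintf("  %d delays, %d repetitions, seed %d\n",
              length(x$schedule$delays), x$schedule$repetitions, x$seed))
  invisible(x)
}

# extract frame i of a run as a pattern1d
run_frame <- function(run, i) {
  pattern1d(run$q, run$I[i, ], run$sigma[i, ],
            meta = list(delay = run$manifest$delay[i],
                        is_reference = as.logical(
                          run$manifest$is_reference[i])))
}

#' Write a simulated run to a directory of pattern files
#'
#' One 3-column `.dat` file per frame plus a `manifest.csv` with the frame
#' index, delay, reference flag and ground-truth corruption label.
#'
#' @param run an `"xss_run"` from [simulate_run()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "xss_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(run$manifest))) {
    write_pattern(run_frame(run, i),
                  file.path(dir, sprintf("frame_%04d.dat", i)))
  }
  utils::write.csv(run$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a run directory written by [write_run()]
#'
#' @param dir directory containing `frame_*.dat` and `manifest.csv`.
#' @return an `"xss_run"` (without generator settings).
#' @export
read_run <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  pats <- lapply(manifest$frame, function(i) {
    read_pattern(file.path(dir, sprintf("frame_%04d.dat", i)))
  })
  q <- pats[[1]]$q
  for (p in pats) {
    if (length(p$q) != length(q) || any(p$q != q)) {
      stop("frames in ", dir, " do not share a common q grid")
    }
  }
  structure(list(q = q,
                 I = do.call(rbind, lapply(pats, `[[`, "I")),
                 sigma = do.call(rbind, lapply(pats, `[[`, "sigma")),
                 manifest = manifest),
            class = "xss_run")
}

#' Render a 1D pattern onto a synthetic detector image
#'
#' Inverse of azimuthal averaging, for reduction round-trip tests: every
#' unmasked pixel receives the pattern intensity interpolated at the
#' pixel's q, with Poisson counting noise at `photon_scale` counts per
#' intensity unit (`photon_scale = Inf` disables the noise and returns the
#' interpolated values directly).
#'
#' @param pattern a [pattern1d()] covering the q-range subtended by the
#'   detector.
#' @param geometry an [experiment_geometry()].
#' @param photon_scale expected counts per intensity unit (default `Inf`).
#' @param mask logical matrix of valid pixels (default all valid).
#' @return a [detector_image()]; masked pixels are zero.
#' @export
render_image <- function(pattern, geometry, photon_scale = Inf,
                         mask = NULL) {
  stopifnot(inherits(pattern, "pattern1d"))
  qm <- q_map(geometry)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(qm), ncol(qm))
  qv <- qm[mask]
  if (min(qv) < min(pattern$q) || max(qv) > max(pattern$q)) {
    stop("pattern q-range [", signif(min(pattern$q), 4), ", ",
         signif(max(pattern$q), 4),
         "] does not cover the detector q-range [",
         signif(min(qv), 4), ", ", signif(max(qv), 4), "]")
  }
  vals <- stats::approx(pattern$q, pattern$I, xout = qv)$y
  if (is.finite(photon_scale)) {
    vals <- stats::rpois(length(vals), pmax(vals, 0) * photon_scale) /
      photon_scale
  }
  counts <- matrix(0, nrow(qm), ncol(qm))
  counts[mask] <- vals
  detector_image(counts, geometry, mask = mask,
                 delay = if (!is.null(pattern$meta$delay))
                   pattern$meta$delay else NA_real_)
}

#' Simulate a noisy structural-parameter delay series
#'
#' Direct generator of an observable-level delay series (bypassing the
#' scattering stage): the trajectory is evaluated at the scheduled delays,
#' baseline subtracted, and i.i.d. Gaussian noise of s.d. `noise_sd` is
#' added; the stated per-point error equals `noise_sd`.
#'
#' @param schedule a [delay_schedule()] (only the delays are used).
#' @param params a [trajectory_params()].
#' @param observable `"dRg"` (default) or `"dVp"`.
#' @param noise_sd Gaussian noise s.d. in observable units (default 0.1 A
#'   for `dRg`, 10 A^3 for `dVp`).
#' @param seed integer RNG seed.
#' @return a `"delay_series"` data frame (`delay`, `value`, `error`).
#' @export
simulate_delay_series <- function(schedule = delay_schedule(),
                                  params = trajectory_params(),
                                  observable = c("dRg", "dVp"),
                                  noise_sd = NULL, seed = 1) {
  observable <- match.arg(observable)
  if (is.null(noise_sd)) noise_sd <- if (observable == "dRg") 0.1 else 10
  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(seed)
  t <- schedule$delays
  truth <- if (observable == "dRg") {
    rg_trajectory(t, params) - params$Rg0
  } else {
    vp_trajectory(t, params) - params$Vp0
  }
  structure(data.frame(delay = t,
                       value = truth + stats::rnorm(length(t), 0, noise_sd),
                       error = rep(noise_sd, length(t))),
            observable = observable,
            class = c("delay_series", "data.frame"))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
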