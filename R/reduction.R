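#' Normalization window
#'
#' The q-window over which every pattern is scaled to a common level
#' before differencing. The default, 1.4 +/- 0.1 inverse Angstrom, sits on
#' the solvent peak shoulder where the protein Guinier term is negligible,
#' so laser-on and reference frames normalize to the same level and the
#' sub-percent photoinduced signal survives the subtraction.
#'
#' @param center window center, inverse Angstrom (default 1.4).
#' @param half_width window half width (default 0.1); `center - half_width`
#'   must be positive.
#' @return an object of class `"norm_window"`.
#' @export
norm_window <- function(center = 1.4, half_width = 0.1) {
  if (center - half_width <= 0) {
    stop("norm_window: center - half_width must be > 0")
  }
  structure(list(center = center, half_width = half_width),
            class = "norm_window")
}

#' Normalize a pattern over a q-window
#'
#' Scales `I` and `sigma` by one factor so that the mean intensity over
#' the window equals 1. The scale factor (the pre-normalization window
#' mean) is recorded in `meta$norm_scale`.
#'
#' @param pattern a [pattern1d()].
#' @param window a [norm_window()].
#' @return the normalized [pattern1d()].
#' @export
normalize_pattern <- function(pattern, window = norm_window()) {
  stopifnot(inherits(pattern, "pattern1d"),
            inherits(window, "norm_window"))
  lo <- window$center - window$half_width
  hi <- window$center + window$half_width
  if (min(pattern$q) > lo || max(pattern$q) < hi) {
    stop("normalization window [", lo, ", ", hi,
         "] outside pattern q-range")
  }
  sel <- pattern$q >= lo & pattern$q <= hi
  m <- mean(pattern$I[sel])
  if (!is.finite(m) || m <= 0) {
    stop("non-positive mean intensity in the normalization window")
  }
  out <- pattern
  out$I <- pattern$I / m
  out$sigma <- pattern$sigma / m
  out$meta$norm_scale <- m * if (!is.null(pattern$meta$norm_scale)) {
    pattern$meta$norm_scale
  } else 1
  out
}

#' Pair laser-on frames with their nearest reference frame
#'
#' Each laser-on frame is paired with the reference frame nearest in
#' acquisition order (ties resolved toward the earlier reference), as in
#' an interleaved-reference acquisition.
#'
#' @param is_reference logical vector in acquisition order.
#' @return data frame with columns `frame` (laser-on index) and `reference`
#'   (paired reference index).
#' @export
pair_with_reference <- function(is_reference) {
  is_reference <- as.logical(is_reference)
  refs <- which(is_reference)
  if (length(refs) == 0) stop("no reference frames")
  ons <- which(!is_reference)
  paired <- vapply(ons, function(i) {
    d <- abs(refs - i)
    refs[which.min(d)]  # which.min takes the first = earlier on ties
  }, integer(1))
  data.frame(frame = ons, reference = paired)
}

#' Iterative reduced-chi-square screening of difference frames
#'
#' Flags outlier difference frames at one delay: each frame's reduced
#' chi-square against the running mean of the accepted frames,
#' \deqn{\chi^2_{red}(i) = \frac{1}{N_q}\sum_q
#'   \frac{(\Delta I_i(q) - \langle\Delta I(q)\rangle)^2}{\sigma_i(q)^2},}
#' is compared with `threshold`; frames above it are rejected, the mean is
#' recomputed over the survivors, and the screen repeats until no new
#' rejection (a fixed point). Set `iterate = FALSE` for a single pass
#' against the all-frame mean.
#'
#' @param dI matrix of difference intensities, frames in rows, common
#'   q-grid in columns (>= 3 rows).
#' @param sigma matrix of per-frame 1-s.d. uncertainties (> 0).
#' @param threshold reduced-chi-square rejection threshold (default 2).
#' @param iterate recompute the mean after each rejection round
#'   (default `TRUE`).
#' @return an object of class `"outlier_report"`: list with `chi2red`
#'   (final per-frame values), `threshold`, `accepted`, `rejected`,
#'   `rejection_fraction`, `iterations`.
#' @export
chi2_screen <- function(dI, sigma, threshold = 2, iterate = TRUE) {
  dI <- as.matrix(dI); sigma <- as.matrix(sigma)
  if (nrow(dI) < 3) stop("need at least 3 difference frames to screen")
  if (!all(dim(sigma) == dim(dI))) stop("sigma shape mismatch")
  if (any(sigma <= 0)) stop("sigma must be > 0 on all bins")
  accepted <- rep(TRUE, nrow(dI))
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    mu <- colMeans(dI[accepted, , drop = FALSE])
    chi2 <- rowMeans(sweep(dI, 2, mu)^2 / sigma^2)
    new_accepted <- accepted & (chi2 <= threshold)
    if (!any(new_accepted)) stop("chi2 screen rejected every frame")
    if (identical(new_accepted, accepted) || !iterate) {
      accepted <- new_accepted
      break
    }
    accepted <- new_accepted
  }
  structure(list(chi2red = chi2, threshold = threshold,
                 accepted = which(accepted), rejected = which(!accepted),
                 rejection_fraction = mean(!accepted),
                 iterations = iterations),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(paste0("chi2 screen: %d/%d frames rejected (%.1f%%), ",
                     "threshold %.3g, %d iteration(s)\n"),
              length(x$rejected),
              length(x$rejected) + length(x$accepted),
              100 * x$rejection_fraction, x$threshold, x$iterations))
  invisible(x)
}

#' Average accepted difference frames
#'
#' Per-bin mean of the accepted difference frames with the standard error
#' of the mean as uncertainty.
#'
#' @param dI matrix of accepted difference intensities (frames in rows).
#' @param q common q grid.
#' @param meta metadata list attached to the result (delay etc.).
#' @return a [pattern1d()] with `meta$n_accepted` set; for a single frame
#'   `sigma` must be supplied via `frame_sigma`.
#' @param frame_sigma optional per-frame sigma matrix; used only when a
#'   single frame is averaged (its own sigma is then returned).
#' @export
average_differences <- function(dI, q, meta = list(), frame_sigma = NULL) {
  dI <- as.matrix(dI)
  if (nrow(dI) == 0) stop("no accepted frames to average")
  n <- nrow(dI)
  m <- colMeans(dI)
  s <- if (n > 1) {
    apply(dI, 2, stats::sd) / sqrt(n)
  } else if (!is.null(frame_sigma)) {
    as.numeric(frame_sigma)
  } else {
    rep(0, ncol(dI))
  }
  meta$n_accepted <- n
  pattern1d(q, m, s, meta = meta)
}

#' Reduce a raw run to averaged, screened difference patterns
#'
#' The full reduction chain: every frame is normalized over the window,
#' each laser-on frame is differenced against its nearest reference frame,
#' the per-delay difference stacks are screened by iterative reduced
#' chi-square, and the survivors are averaged. Because every laser-on
#' frame in a block shares its paired reference with its neighbours, the
#' per-bin uncertainty of the average is propagated from the stated
#' per-frame uncertainties through the pairing weights rather than taken
#' as the naive standard error (which would understate it). The mean
#' reference normalization factor is recorded per delay
#' (`meta$norm_scale`) so the differences can be restored to the counts
#' scale by [fit_difference()].
#'
#' @param run an `"xss_run"` (from [simulate_run()] or [read_run()]).
#' @param window a [norm_window()].
#' @param threshold reduced-chi-square screen threshold; `Inf` keeps all.
#' @param screen logical; `FALSE` skips the screen entirely (e.g. for
#'   noiseless data whose sigma is zero).
#' @param iterate passed to [chi2_screen()].
#' @return an object of class `"xss_reduced"`: list with `patterns` (one
#'   averaged difference [pattern1d()] per delay, in delay order) and
#'   `reports` (per-delay data frame: delay, n_total, n_rejected,
#'   threshold, plus the [chi2_screen()] reports).
#' @export
reduce_run <- function(run, window = norm_window(), threshold = 2,
                       screen = TRUE, iterate = TRUE) {
  q <- run$q
  man <- run$manifest
  lo <- window$center - window$half_width
  hi <- window$center + window$half_width
  if (min(q) > lo || max(q) < hi) {
    stop("normalization window outside the run q-range")
  }
  sel <- q >= lo & q <= hi
  scale <- rowMeans(run$I[, sel, drop = FALSE])
  if (any(scale <= 0)) stop("non-positive normalization window mean")
  In <- run$I / scale
  Sn <- run$sigma / scale

  pairs <- pair_with_reference(man$is_reference)
  dI_all <- In[pairs$frame, , drop = FALSE] -
    In[pairs$reference, , drop = FALSE]
  sig_all <- sqrt(Sn[pairs$frame, , drop = FALSE]^2 +
                    Sn[pairs$reference, , drop = FALSE]^2)

  delays <- sort(unique(man$delay[!man$is_reference]))
  patterns <- list()
  report_rows <- list()
  reports <- list()
  for (k in seq_along(delays)) {
    d <- delays[k]
    rows <- which(man$delay[pairs$frame] == d)
    dI <- dI_all[rows, , drop = FALSE]
    sg <- sig_all[rows, , drop = FALSE]
    if (screen && length(rows) >= 3) {
      rep_k <- chi2_screen(dI, sg, threshold = threshold,
                           iterate = iterate)
      acc <- rep_k$accepted
    } else {
      rep_k <- NULL
      acc <- seq_len(length(rows))
    }
    meta <- list(delay = d,
                 norm_scale = mean(scale[pairs$reference[rows[acc]]]))
    patterns[[k]] <- average_differences(
      dI[acc, , drop = FALSE], q, meta = meta,
      frame_sigma = if (length(acc) == 1) sg[acc, ] else NULL)
    # the naive standard error treats the differences as independent, but
    # frames paired to the same reference share its noise; propagate the
    # stated per-frame uncertainties through the pairing weights instead
    on_idx <- pairs$frame[rows[acc]]
    ref_idx <- pairs$reference[rows[acc]]
    n_acc <- length(acc)
    var_prop <- colSums(Sn[on_idx, , drop = FALSE]^2) / n_acc^2
    for (r in unique(ref_idx)) {
      w_r <- sum(ref_idx == r) / n_acc
      var_prop <- var_prop + w_r^2 * Sn[r, ]^2
    }
    if (any(var_prop > 0)) patterns[[k]]$sigma <- sqrt(var_prop)
    reports[[k]] <- rep_k
    report_rows[[k]] <- data.frame(
      delay = d, n_total = length(rows),
      n_rejected = length(rows) - length(acc),
      threshold = if (screen) threshold else NA_real_)
  }
  structure(list(patterns = patterns,
                 summary = do.call(rbind, report_rows),
                 reports = reports,
                 window = window),
            class = "xss_reduced")
}

#' @export
print.xss_reduced <- function(x, ...) {
  cat(sprintf("Reduced run: %d delays\n", length(x$patterns)))
  print(x$summary)
  invisible(x)
}

#' Azimuthal average of a detector image
#'
#' Groups unmasked pixels into q-bins and returns the per-bin mean
#' intensity with the standard deviation over the bin's pixels divided by
#' the square root of the pixel count as uncertainty. Empty bins are
#' dropped from the result and listed in `attr(, "empty_bins")`.
#'
#' @param image a [detector_image()].
#' @param q_bins bin edges in inverse Angstrom (length nbins + 1), or a
#'   single integer number of equal-width bins over the detector q-range.
#' @return a [pattern1d()] with q at the bin midpoints.
#' @export
azimuthal_average <- function(image, q_bins = 200L) {
  stopifnot(inherits(image, "detector_image"))
  if (!any(image$mask)) stop("fully masked image")
  qm <- q_map(image$geometry)
  qv <- qm[image$mask]
  cv <- image$counts[image$mask]
  if (length(q_bins) == 1L) {
    q_bins <- seq(min(qv), max(qv) * (1 + 1e-12),
                  length.out = as.integer(q_bins) + 1L)
  }
  nb <- length(q_bins) - 1L
  bin <- findInterval(qv, q_bins, rightmost.closed = TRUE)
  inside <- bin >= 1 & bin <= nb
  bin <- bin[inside]; cv <- cv[inside]
  if (length(cv) == 0) stop("no unmasked pixels fall inside the q bins")
  n <- tabulate(bin, nbins = nb)
  # rowsum orders by the factor levels present; rebuild dense vectors
  present <- sort(unique(bin))
  sum_v <- numeric(nb); sum_v[present] <- rowsum(cv, bin)[, 1]
  mean_v <- ifelse(n > 0, sum_v / pmax(n, 1), NA_real_)
  # two-pass variance: centred squares avoid catastrophic cancellation
  sqdev <- numeric(nb)
  sqdev[present] <- rowsum((cv - mean_v[bin])^2, bin)[, 1]
  var_v <- ifelse(n > 1, sqdev / (n - 1), 0)
  sem <- ifelse(n > 0, sqrt(pmax(var_v, 0) / pmax(n, 1)), NA_real_)
  mid <- (q_bins[-1] + q_bins[-(nb + 1)]) / 2
  keep <- n > 0
  out <- pattern1d(mid[keep], mean_v[keep], sem[keep],
                   meta = list(delay = image$delay))
  attr(out, "empty_bins") <- which(!keep)
  out
}
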