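#' One-dimensional scattering pattern
#'
#' A `pattern1d` holds a scattering curve: a strictly increasing q grid
#' (inverse Angstrom), per-bin intensities (detector counts, arbitrary
#' scale) and 1-s.d. uncertainties, plus free-form metadata (pump--probe
#' delay in ps, accumulation count, normalization scale, ...).
#'
#' @param q strictly increasing, non-negative momentum-transfer grid.
#' @param I intensities, same length as `q`.
#' @param sigma 1-s.d. uncertainties, non-negative, same length as `q`.
#' @param meta named list of metadata (e.g. `delay`, `n_accepted`).
#' @return an object of class `"pattern1d"`.
#' @export
pattern1d <- function(q, I, sigma = NULL, meta = list()) {
  q <- as.numeric(q); I <- as.numeric(I)
  if (is.null(sigma)) sigma <- rep(0, length(q))
  sigma <- as.numeric(sigma)
  if (length(I) != length(q) || length(sigma) != length(q)) {
    stop("q, I and sigma must have equal length")
  }
  if (any(q < 0)) stop("q must be non-negative")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (any(sigma < 0)) stop("sigma must be non-negative")
  structure(list(q = q, I = I, sigma = sigma, meta = meta),
            class = "pattern1d")
}

#' @export
print.pattern1d <- function(x, ...) {
  cat(sprintf("1D scattering pattern: %d bins, q in [%.4g, %.4g] 1/A\n",
              length(x$q), min(x$q), max(x$q)))
  if (!is.null(x$meta$delay)) {
    cat(sprintf("  delay: %g ps\n", x$meta$delay))
  }
  invisible(x)
}

#' @export
as.data.frame.pattern1d <- function(x, ...) {
  data.frame(q = x$q, I = x$I, sigma = x$sigma)
}

# format a metadata value for the '#' header
.meta_fmt <- function(v) {
  if (is.numeric(v)) paste(format(v, digits = 17), collapse = " ")
  else paste(as.character(v), collapse = " ")
}

#' Read and write 1D patterns as 3-column text
#'
#' The on-disk dialect is plain whitespace- or comma-separated text with
#' three columns `q I sigma` (two columns are accepted: sigma is then
#' synthesized as Poisson, `sqrt(I)`, with a warning) and `#`-prefixed
#' header comments of the form `# key: value` carrying the metadata.
#' A write followed by a read reproduces the arrays to full stored
#' precision.
#'
#' @param path file path.
#' @return `read_pattern` returns a [pattern1d()].
#' @export
read_pattern <- function(path) {
  lines <- readLines(path)
  meta <- list()
  is_comment <- grepl("^\\s*#", lines)
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", cl))[[1]]
    if (length(m) == 3) {
      key <- trimws(m[2]); val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(strsplit(val, "\\s+")[[1]]))
      meta[[key]] <- if (!anyNA(num)) num else val
    }
  }
  data_lines <- which(!is_comment & nzchar(trimws(lines)))
  if (length(data_lines) == 0) stop("no data rows in ", path)
  rows <- lapply(data_lines, function(i) {
    fields <- strsplit(trimws(gsub(",", " ", lines[i])), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) stop("non-numeric field on line ", i, " of ", path)
    vals
  })
  ncol <- lengths(rows)
  if (any(ncol != ncol[1])) {
    bad <- data_lines[which(ncol != ncol[1])[1]]
    stop("row length mismatch on line ", bad, " of ", path)
  }
  tab <- do.call(rbind, rows)
  if (ncol[1] == 2L) {
    warning("2-column pattern file: synthesizing sigma = sqrt(I) (Poisson)")
    tab <- cbind(tab, sqrt(pmax(tab[, 2], 0)))
  } else if (ncol[1] != 3L) {
    stop("expected 2 or 3 columns, got ", ncol[1], " in ", path)
  }
  if (any(diff(tab[, 1]) <= 0)) {
    bad <- data_lines[which(diff(tab[, 1]) <= 0)[1] + 1L]
    stop("q not strictly increasing at line ", bad, " of ", path)
  }
  if (any(tab[, 3] < 0)) {
    bad <- data_lines[which(tab[, 3] < 0)[1]]
    stop("negative sigma on line ", bad, " of ", path)
  }
  pattern1d(tab[, 1], tab[, 2], tab[, 3], meta = meta)
}

#' @rdname read_pattern
#' @param pattern a [pattern1d()].
#' @export
write_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "pattern1d"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# columns: q[1/A] I sigma", con)
  for (key in names(pattern$meta)) {
    writeLines(sprintf("# %s: %s", key, .meta_fmt(pattern$meta[[key]])), con)
  }
  writeLines(sprintf("%.17g %.17g %.17g",
                     pattern$q, pattern$I, pattern$sigma), con)
  invisible(path)
}

#' Two-dimensional detector image
#'
#' @param counts matrix of non-negative pixel values matching
#'   `geometry$detector_shape`.
#' @param geometry an [experiment_geometry()].
#' @param mask logical matrix, `TRUE` = valid pixel; defaults to all valid.
#' @param delay pump--probe delay in ps, or `NA`.
#' @return an object of class `"detector_image"`.
#' @export
detector_image <- function(counts, geometry, mask = NULL, delay = NA_real_) {
  stopifnot(inherits(geometry, "experiment_geometry"))
  counts <- as.matrix(counts)
  if (!all(dim(counts) == geometry$detector_shape)) {
    stop("counts shape does not match geometry$detector_shape")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(counts), ncol(counts))
  if (!all(dim(mask) == dim(counts))) stop("mask shape mismatch")
  if (any(counts[mask] < 0)) stop("negative counts on unmasked pixels")
  structure(list(counts = counts, mask = mask, geometry = geometry,
                 delay = delay),
            class = "detector_image")
}

#' Read and write detector images as 16-bit TIFF
#'
#' Detector frames are stored as single-channel 16-bit unsigned integer
#' TIFF (the native depth of typical CCD detectors); counts must be
#' integers in `[0, 65535]`. Reading returns the raw integer counts with an
#' all-valid mask.
#'
#' @param path TIFF file path.
#' @param geometry an [experiment_geometry()] describing the frame.
#' @param delay pump--probe delay in ps attached to the image.
#' @return `read_image` returns a [detector_image()].
#' @export
read_image <- function(path, geometry, delay = NA_real_) {
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) stop("cannot read TIFF ", path, ": ",
                                           conditionMessage(e)))
  if (length(dim(img)) != 2L) stop("TIFF payload in ", path, " is not 2D")
  read_geom <- geometry
  if (!all(dim(img) == read_geom$detector_shape)) {
    stop("image shape ", paste(dim(img), collapse = "x"),
         " does not match geometry")
  }
  detector_image(img, read_geom, delay = delay)
}

#' @rdname read_image
#' @param image a [detector_image()].
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "detector_image"))
  cnt <- image$counts
  if (any(cnt != round(cnt)) || any(cnt < 0) || any(cnt > 65535)) {
    stop("counts must be integers in [0, 65535] for 16-bit TIFF output")
  }
  tiff::writeTIFF(cnt / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
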