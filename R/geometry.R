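#' Experiment geometry for a flat area detector
#'
#' Describes the pump--probe scattering geometry: X-ray wavelength/energy,
#' normal sample--detector distance, detector pixel grid and beam center.
#' Wavelength and photon energy must agree through
#' \eqn{\lambda[\AA] = 12.3984 / E[keV]} to within 0.1%; if only one of the
#' two is given the other is derived.
#'
#' The detector is assumed flat and normal to the beam (no tilt refinement),
#' and pixel \code{(i, j)} samples its geometric center, with the beam center
#' given in fractional pixel coordinates.
#'
#' @param photon_energy_keV photon energy in keV (default 9).
#' @param wavelength_A X-ray wavelength in Angstrom; derived from the energy
#'   when `NULL`.
#' @param distance_cm sample--detector distance in cm (default 16.8).
#' @param pixel_size_um pixel pitch in micrometer (default 80).
#' @param detector_shape integer vector `c(nx, ny)` of pixels (default
#'   `c(2048, 2048)`).
#' @param beam_center beam center `c(x, y)` in fractional pixels; defaults to
#'   the detector center.
#' @return an object of class `"experiment_geometry"`.
#' @examples
#' g <- experiment_geometry()
#' pixel_to_q(10, g)   # q at 10 mm from the beam center
#' @export
experiment_geometry <- function(photon_energy_keV = 9,
                                wavelength_A = NULL,
                                distance_cm = 16.8,
                                pixel_size_um = 80,
                                detector_shape = c(2048L, 2048L),
                                beam_center = (detector_shape + 1) / 2) {
  if (is.null(wavelength_A)) {
    wavelength_A <- energy_to_wavelength(photon_energy_keV)
  } else if (is.null(photon_energy_keV)) {
    photon_energy_keV <- wavelength_to_energy(wavelength_A)
  } else {
    rel <- abs(wavelength_A - energy_to_wavelength(photon_energy_keV)) /
      wavelength_A
    if (rel > 1e-3) {
      stop("wavelength_A and photon_energy_keV are inconsistent (>0.1%): ",
           signif(wavelength_A, 6), " vs ",
           signif(energy_to_wavelength(photon_energy_keV), 6), " Angstrom")
    }
  }
  stopifnot(wavelength_A > 0, distance_cm > 0, pixel_size_um > 0)
  detector_shape <- as.integer(detector_shape)
  if (length(detector_shape) != 2L || any(detector_shape < 1L)) {
    stop("detector_shape must be two positive integers")
  }
  if (length(beam_center) != 2L ||
      any(beam_center < 0.5) || any(beam_center > detector_shape + 0.5)) {
    stop("beam_center must lie inside detector_shape")
  }
  structure(
    list(photon_energy_keV = photon_energy_keV,
         wavelength_A = wavelength_A,
         distance_cm = distance_cm,
         pixel_size_um = pixel_size_um,
         detector_shape = detector_shape,
         beam_center = as.numeric(beam_center)),
    class = "experiment_geometry")
}

#' @export
print.experiment_geometry <- function(x, ...) {
  cat("Experiment geometry\n")
  cat(sprintf("  photon energy : %.4g keV (lambda = %.4f A)\n",
              x$photon_energy_keV, x$wavelength_A))
  cat(sprintf("  distance      : %.3g cm\n", x$distance_cm))
  cat(sprintf("  detector      : %d x %d pixels, %.3g um pitch\n",
              x$detector_shape[1], x$detector_shape[2], x$pixel_size_um))
  cat(sprintf("  beam center   : (%.2f, %.2f) px\n",
              x$beam_center[1], x$beam_center[2]))
  invisible(x)
}

#' Photon energy to wavelength conversion
#'
#' \eqn{\lambda[\AA] = 12.3984 / E[keV]}; the two functions are exact
#' inverses of each other.
#'
#' @param energy_keV photon energy in keV.
#' @return wavelength in Angstrom.
#' @export
energy_to_wavelength <- function(energy_keV) {
  stopifnot(all(energy_keV > 0))
  12.3984 / energy_keV
}

#' @rdname energy_to_wavelength
#' @param wavelength_A wavelength in Angstrom.
#' @export
wavelength_to_energy <- function(wavelength_A) {
  stopifnot(all(wavelength_A > 0))
  12.3984 / wavelength_A
}

#' Radial detector position to momentum transfer
#'
#' Converts the distance of a detector pixel from the beam center into
#' momentum transfer \eqn{q = 4\pi/\lambda \sin(\theta/2)} with the
#' scattering angle \eqn{\theta = \arctan(r / D)} for a flat detector at
#' normal distance \eqn{D}. Strictly increasing in the radius.
#'
#' @param radius_mm radial distance from the beam center, mm (vectorised).
#' @param geometry an [experiment_geometry()].
#' @return momentum transfer in inverse Angstrom.
#' @export
pixel_to_q <- function(radius_mm, geometry) {
  stopifnot(inherits(geometry, "experiment_geometry"))
  if (any(radius_mm < 0)) stop("radius_mm must be non-negative")
  theta <- atan2(radius_mm, geometry$distance_cm * 10)
  4 * pi / geometry$wavelength_A * sin(theta / 2)
}

#' Per-pixel momentum transfer map
#'
#' @param geometry an [experiment_geometry()].
#' @return matrix (nx by ny) of q values at each pixel center, inverse
#'   Angstrom.
#' @export
q_map <- function(geometry) {
  stopifnot(inherits(geometry, "experiment_geometry"))
  px_mm <- geometry$pixel_size_um / 1000
  nx <- geometry$detector_shape[1]
  ny <- geometry$detector_shape[2]
  dx <- (seq_len(nx) - geometry$beam_center[1]) * px_mm
  dy <- (seq_len(ny) - geometry$beam_center[2]) * px_mm
  r <- sqrt(outer(dx^2, dy^2, `+`))
  matrix(pixel_to_q(as.vector(r), geometry), nx, ny)
}
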