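# small fixtures shared across test files; everything is built in code

tiny_geometry <- function(n = 64L, pixel_mm = 2.5) {
  experiment_geometry(photon_energy_keV = 9, distance_cm = 16.8,
                      pixel_size_um = pixel_mm * 1000,
                      detector_shape = c(n, n))
}

paper_schedule <- function() {
  delay_schedule(delays = c(seq(-3, 10, by = 0.5), seq(15, 50, by = 5)))
}

# an independent numerical convolution oracle (quadrature, not the
# closed-form path used by the package)
conv_oracle <- function(t, fn, fwhm) {
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  vapply(t, function(ti) {
    stats::integrate(function(u) fn(ti - u) * stats::dnorm(u, 0, sig),
                     lower = -8 * sig, upper = 8 * sig,
                     rel.tol = 1e-10)$value
  }, numeric(1))
}
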