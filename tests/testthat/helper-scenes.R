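# Shared synthetic-scene builders for the test suite.  All fixtures are
# generated in code; the study conditions are a 500 um (or 100 um) period
# grid and a chrome-on-glass USAF chart imaged at M ~ 0.5-1.5 onto a
# 1.2 um-pitch sensor.

SNR50_NOISE <- (0.95 - 0.1) / 50  # read-noise SD giving edge SNR 50

grid_scene <- function(M = 1, fwhm = 0, seed = 1, noise = 0, k1 = 0,
                       period = 500, size = NULL) {
  if (is.null(size)) size <- ceiling(2.2 * period * M / 1.2) + 60
  scene_config(magnification = M, pixel_pitch = 1.2, psf_fwhm = fwhm,
               distortion_k1 = k1, read_noise_sd = noise, seed = seed,
               image_size = c(size, size))
}

make_grid <- function(M = 1, fwhm = 0, seed = 1, noise = 0, k1 = 0,
                      period = 500, line_width = period / 10, size = NULL) {
  render_grid(grid_target_spec(period, line_width),
              grid_scene(M, fwhm, seed, noise, k1, period, size))
}

# single USAF element 4-2 (vertical bars), sized to fit with margin
make_usaf42 <- function(M = 1, fwhm = 0, seed = 1, noise = 0) {
  size <- ceiling(10 * 27.84 * M / 1.2) + 40
  sc <- scene_config(magnification = M, pixel_pitch = 1.2, psf_fwhm = fwhm,
                     read_noise_sd = noise, seed = seed,
                     image_size = c(size, size))
  render_usaf(sc, groups = 4, elements = 2, orientations = "vertical")
}

# analytic Gaussian-blurred edge as a finely sampled sensor-plane profile
analytic_edge_profile <- function(fwhm_sample, magnification,
                                  pixel_pitch = 1.2, refine = 8,
                                  half_width_sigmas = 8) {
  sigma <- fwhm_sample * magnification / (2 * sqrt(2 * log(2)))  # sensor um
  h <- pixel_pitch / refine
  x <- seq(0, 2 * half_width_sigmas * sigma, by = h)
  x0 <- mean(x) + 0.3 * h  # off-grid edge position
  line_profile(x, pnorm((x - x0) / sigma), plane = "sensor")
}
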