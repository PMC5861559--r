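#' Forward imaging model configuration
#'
#' Bundles every parameter of the synthetic imaging chain: geometric
#' magnification onto the sensor, sensor pixel pitch, the blur model,
#' radial distortion, vignetting, and sensor noise.  A scene plus a seed
#' fully determines a rendered image, bit for bit.
#'
#' The default pixel pitch (1.2 um) matches a typical small-pixel smartphone
#' sensor (e.g. the Sony IMX220).
#'
#' @param magnification Sample-to-sensor scale M (> 0, unitless).
#' @param pixel_pitch Sensor pixel pitch in micrometers.
#' @param psf_model `"gaussian"` or `"airy"`.
#' @param psf_fwhm Gaussian PSF full width at half maximum, in sample-plane
#'   micrometers (used when `psf_model = "gaussian"`; 0 disables blur).
#' @param na Numerical aperture (used when `psf_model = "airy"`).
#' @param wavelength Wavelength in nanometers (used when `psf_model = "airy"`).
#' @param distortion_k1 Radial distortion coefficient of the one-term Brown
#'   model `r' = r (1 + k1 r^2)` with `r` normalized by the half-diagonal of
#'   the image; positive values give pincushion distortion.
#' @param vignette_strength Strength `v` of the multiplicative falloff
#'   `1 - v r^2` (normalized radius), in `[0, 1]`.
#' @param read_noise_sd Additive Gaussian read noise standard deviation, in
#'   intensity units.
#' @param photon_gain Electrons per intensity unit for Poisson shot noise;
#'   0 disables shot noise.
#' @param seed Integer seed controlling both noise sources.
#' @param image_size Sensor image size in pixels, `c(rows, cols)`.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(magnification = 1,
                         pixel_pitch = 1.2,
                         psf_model = c("gaussian", "airy"),
                         psf_fwhm = 0,
                         na = NULL,
                         wavelength = 550,
                         distortion_k1 = 0,
                         vignette_strength = 0,
                         read_noise_sd = 0,
                         photon_gain = 0,
                         seed = 1L,
                         image_size = c(512L, 512L)) {
  psf_model <- match.arg(psf_model)
  check_positive_scalar(magnification, "magnification")
  check_positive_scalar(pixel_pitch, "pixel_pitch")
  if (!is_scalar_number(psf_fwhm) || psf_fwhm < 0) {
    stop_domain("`psf_fwhm` must be a single non-negative number")
  }
  if (psf_model == "airy") {
    check_positive_scalar(na, "na")
    check_positive_scalar(wavelength, "wavelength")
  }
  if (!is_scalar_number(vignette_strength) ||
      vignette_strength < 0 || vignette_strength > 1) {
    stop_domain("`vignette_strength` must be in [0, 1]")
  }
  if (!is_scalar_number(read_noise_sd) || read_noise_sd < 0) {
    stop_domain("`read_noise_sd` must be non-negative")
  }
  if (!is_scalar_number(photon_gain) || photon_gain < 0) {
    stop_domain("`photon_gain` must be non-negative")
  }
  image_size <- as.integer(image_size)
  if (length(image_size) != 2 || any(image_size < 2)) {
    stop_domain("`image_size` must be two integers (rows, cols), each >= 2")
  }
  structure(
    list(magnification = magnification, pixel_pitch = pixel_pitch,
         psf_model = psf_model, psf_fwhm = psf_fwhm,
         na = if (is.null(na)) NULL else na, wavelength = wavelength,
         distortion_k1 = distortion_k1,
         vignette_strength = vignette_strength,
         read_noise_sd = read_noise_sd, photon_gain = photon_gain,
         seed = as.integer(seed), image_size = image_size),
    class = "scene_config"
  )
}

#' @export
print.scene_config <- function(x, ...) {
  cat("<scene_config>\n")
  cat(sprintf("  magnification %.3g, pixel pitch %.3g um, image %d x %d px\n",
              x$magnification, x$pixel_pitch, x$image_size[1], x$image_size[2]))
  if (x$psf_model == "gaussian") {
    cat(sprintf("  PSF: gaussian, FWHM %.3g um (sample plane)\n", x$psf_fwhm))
  } else {
    cat(sprintf("  PSF: airy, NA %.3g at %g nm\n", x$na, x$wavelength))
  }
  cat(sprintf("  distortion k1 %.3g, vignette %.3g, read noise %.3g, photon gain %.3g, seed %d\n",
              x$distortion_k1, x$vignette_strength, x$read_noise_sd,
              x$photon_gain, x$seed))
  invisible(x)
}

#' Serialize or restore a scene configuration
#'
#' Scene configurations round-trip through JSON or YAML (chosen by file
#' extension) so a rendering is reproducible from its sidecar file.
#'
#' @param scene A [scene_config].
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_scene_config` returns `path` invisibly;
#'   `read_scene_config` returns a [scene_config].
#' @export
write_scene_config <- function(scene, path) {
  stopifnot(inherits(scene, "scene_config"))
  x <- unclass(scene)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else {
    stop_domain(sprintf("unsupported config extension '%s'", ext))
  }
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop_domain(sprintf("unsupported config extension '%s'", ext))
  }
  do.call(scene_config, x)
}
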