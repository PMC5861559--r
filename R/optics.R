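#' Apply the forward optics chain to an ideal image
#'
#' Transforms an ideal sample-plane image into the sensor image a real lens
#' and camera would record.  Stages, in order:
#'
#' 1. **Magnification resampling** to the sensor grid (scale factor
#'    `ideal_pitch * M / pixel_pitch`; bilinear).  Images produced by the
#'    built-in renderers are already on the sensor grid, so this step is the
#'    identity for them.
#' 2. **Radial distortion**: a source point at radius `r` from the image
#'    center lands at `r' = r (1 + k1 * (r/Rn)^2)`, with `Rn` the image
#'    half-diagonal; `k1 > 0` gives pincushion.  Implemented by inverse
#'    mapping (Newton solve) with bilinear sampling.
#' 3. **PSF convolution** at sensor resolution.  Gaussian: separable kernel
#'    with `sigma = FWHM / (2 sqrt(2 ln 2))` in sample micrometers scaled to
#'    sensor pixels by `M / pixel_pitch`, truncated at 4 sigma.  Airy: radial
#'    kernel from NA and wavelength with first zero at `0.61 lambda / NA`,
#'    truncated at its third zero.  Kernels are normalized to sum 1 and the
#'    image border is edge-replicated.
#' 4. **Vignetting**: multiplicative `1 - v * (r/Rn)^2`.
#' 5. **Noise**: Poisson shot noise at `photon_gain` electrons per intensity
#'    unit, then additive Gaussian read noise; both driven by the scene seed,
#'    so identical configurations give bit-identical images.  Values are
#'    clamped at zero.
#'
#' @param ideal A [raster_image] on the sample plane (`plane = "sample"`,
#'   `pixel_pitch` in sample micrometers per pixel).
#' @param scene A [scene_config].
#' @return A [raster_image] on the sensor plane.
#' @export
apply_optics <- function(ideal, scene) {
  stopifnot(inherits(ideal, "raster_image"), inherits(scene, "scene_config"))
  img <- as_grayscale(ideal)$intensities
  M <- scene$magnification; pp <- scene$pixel_pitch

  ## 1. resample to the sensor grid
  scale <- ideal$pixel_pitch * M / pp
  if (abs(scale - 1) > 1e-9) {
    new_dim <- pmax(2L, as.integer(round(dim(img) * scale)))
    img <- EBImage::resize(img, w = new_dim[1], h = new_dim[2],
                           filter = "bilinear")
    img <- crop_or_pad(img, scene$image_size)
  }

  ## 2. radial distortion
  if (scene$distortion_k1 != 0) {
    img <- distort_radial(img, scene$distortion_k1)
  }

  ## 3. PSF convolution
  kern <- psf_kernel(scene)
  if (!is.null(kern)) {
    if (is.list(kern)) {                 # separable gaussian
      img <- EBImage::filter2(img, matrix(kern$k, nrow = 1),
                              boundary = "replicate")
      img <- EBImage::filter2(img, matrix(kern$k, ncol = 1),
                              boundary = "replicate")
    } else {
      img <- EBImage::filter2(img, kern, boundary = "replicate")
    }
  }

  ## 4. vignette
  if (scene$vignette_strength > 0) {
    rn2 <- normalized_radius2(dim(img))
    img <- img * (1 - scene$vignette_strength * rn2)
  }

  ## 5. noise
  if (scene$photon_gain > 0 || scene$read_noise_sd > 0) {
    img <- with_local_seed(scene$seed, {
      v <- img
      if (scene$photon_gain > 0) {
        v <- matrix(rpois(length(v), scene$photon_gain * pmax(v, 0)),
                    nrow(v)) / scene$photon_gain
      }
      if (scene$read_noise_sd > 0) {
        v <- v + matrix(rnorm(length(v), 0, scene$read_noise_sd), nrow(v))
      }
      v
    })
  }
  img <- pmax(img, 0)
  raster_image(img, pp, bit_depth = "float", plane = "sensor")
}

## squared radius normalized by the half-diagonal, per pixel
normalized_radius2 <- function(d) {
  cr <- (d[1] - 1) / 2; cc <- (d[2] - 1) / 2
  rn2 <- cr^2 + cc^2
  dr2 <- ((0:(d[1] - 1)) - cr)^2
  dc2 <- ((0:(d[2] - 1)) - cc)^2
  outer(dr2, dc2, "+") / rn2
}

## Inverse-map radial distortion r' = r (1 + k1 (r/Rn)^2): for every output
## pixel at radius rp, Newton-solve for the source radius r and sample the
## input bilinearly along the same direction.
distort_radial <- function(img, k1) {
  if (k1 <= -1 / 3) {
    stop_domain(sprintf(
      "distortion k1 = %.3g makes the radial mapping non-invertible over the field",
      k1))
  }
  d <- dim(img)
  cr <- (d[1] - 1) / 2; cc <- (d[2] - 1) / 2
  Rn <- sqrt(cr^2 + cc^2)
  row <- matrix((0:(d[1] - 1)) - cr, d[1], d[2])
  col <- matrix((0:(d[2] - 1)) - cc, d[1], d[2], byrow = TRUE)
  rp <- sqrt(row^2 + col^2)
  ## Newton iterations for r + k1 r^3 / Rn^2 = rp, starting at r = rp
  r <- rp
  for (it in 1:25) {
    f <- r + k1 * r^3 / Rn^2 - rp
    fp <- 1 + 3 * k1 * r^2 / Rn^2
    r <- r - f / fp
  }
  s <- ifelse(rp > 0, r / rp, 1)
  src_r <- row * s + cr
  src_c <- col * s + cc
  matrix(bilinear_sample(img, src_r, src_c), d[1], d[2])
}

## PSF kernel for a scene: NULL (no blur), list(k=...) for a separable
## gaussian, or a matrix for the airy pattern.
psf_kernel <- function(scene) {
  M <- scene$magnification; pp <- scene$pixel_pitch
  if (scene$psf_model == "gaussian") {
    if (scene$psf_fwhm <= 0) return(NULL)
    sigma_px <- fwhm_to_sigma(scene$psf_fwhm) * M / pp
    if (sigma_px < 1e-4) return(NULL)
    h <- max(1L, ceiling(4 * sigma_px))
    k <- dnorm((-h):h, sd = sigma_px)
    list(k = k / sum(k))
  } else {
    lam_um <- scene$wavelength / 1000
    r1 <- 0.61 * lam_um / scene$na            # first zero, sample um
    r1_px <- r1 * M / pp
    h <- max(1L, ceiling(r1_px * 10.1735 / 3.8317))  # out to the 3rd zero
    idx <- (-h):h
    rr <- sqrt(outer(idx^2, idx^2, "+"))
    v <- 3.8317 * rr / r1_px
    k <- ifelse(v < 1e-12, 1, (2 * besselJ(v, 1) / v)^2)
    k / sum(k)
  }
}

## center-crop or edge-replicate-pad a matrix to the target (rows, cols)
crop_or_pad <- function(img, size) {
  d <- dim(img)
  take <- function(n, target) {
    if (n >= target) {
      off <- (n - target) %/% 2
      seq_len(target) + off
    } else {
      pad0 <- (target - n) %/% 2
      idx <- c(rep(1L, pad0), seq_len(n), rep(n, target - n - pad0))
      idx
    }
  }
  img[take(d[1], size[1]), take(d[2], size[2]), drop = FALSE]
}
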