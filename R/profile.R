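#' Line profile container
#'
#' Positions and intensities sampled along a segment of an image.  Positions
#' are in micrometers of the named plane and must be uniformly spaced.
#'
#' @param positions Strictly increasing, uniformly spaced positions (um).
#' @param intensities Intensities at those positions.
#' @param plane `"sensor"` or `"sample"`.
#' @return An object of class `line_profile`.
#' @export
line_profile <- function(positions, intensities, plane = c("sensor", "sample")) {
  plane <- match.arg(plane)
  if (length(positions) != length(intensities)) {
    stop_domain("`positions` and `intensities` must have equal length")
  }
  if (length(positions) >= 2) {
    d <- diff(positions)
    if (any(d <= 0)) stop_domain("`positions` must be strictly increasing")
    if (diff(range(d)) > 1e-6 * mean(d)) {
      stop_domain("`positions` must be uniformly spaced")
    }
  }
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities),
                 spacing = if (length(positions) >= 2) mean(diff(positions)) else NA_real_,
                 plane = plane),
            class = "line_profile")
}

#' @export
print.line_profile <- function(x, ...) {
  cat(sprintf("<line_profile> %d samples, spacing %.4g um (%s plane)\n",
              length(x$positions), x$spacing, x$plane))
  invisible(x)
}

#' @export
plot.line_profile <- function(x, ...) {
  graphics::plot(x$positions, x$intensities, type = "l",
                 xlab = sprintf("position (um, %s plane)", x$plane),
                 ylab = "intensity", ...)
  invisible(x)
}

#' Extract an intensity cross-section from an image
#'
#' Samples the image along the segment from `p0` to `p1` at one-pixel
#' spacing using bilinear interpolation, optionally averaging over
#' `width_px` parallel lines offset perpendicular to the segment (centered,
#' one-pixel steps).  Positions are reported in micrometers of the image
#' plane (`index * pixel_pitch`).
#'
#' @param image A [raster_image].
#' @param p0,p1 Segment endpoints as 0-based `c(row, col)` pixel coordinates.
#' @param width_px Number of parallel lines to average (odd integer >= 1).
#' @return A [line_profile].
#' @export
extract_profile <- function(image, p0, p1, width_px = 1) {
  stopifnot(inherits(image, "raster_image"))
  image <- as_grayscale(image)
  m <- image$intensities
  nr <- nrow(m); nc <- ncol(m)
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (length(p0) != 2 || length(p1) != 2) {
    stop_domain("`p0` and `p1` must be (row, col) pairs")
  }
  L <- sqrt(sum((p1 - p0)^2))
  if (L < 2) stop_geometry("segment is shorter than two pixels")
  width_px <- as.integer(width_px)
  if (width_px < 1 || width_px %% 2 == 0) {
    stop_domain("`width_px` must be an odd positive integer")
  }
  dir <- (p1 - p0) / L
  perp <- c(-dir[2], dir[1])
  t <- seq(0, floor(L))
  offs <- (seq_len(width_px) - 1) - (width_px - 1) / 2
  rows <- outer(p0[1] + t * dir[1], offs * perp[1], "+")
  cols <- outer(p0[2] + t * dir[2], offs * perp[2], "+")
  if (any(rows < 0 | rows > nr - 1 | cols < 0 | cols > nc - 1)) {
    stop_geometry("profile segment (including width offsets) leaves the image")
  }
  vals <- matrix(bilinear_sample(m, rows, cols), nrow = length(t))
  line_profile(t * image$pixel_pitch, rowMeans(vals), plane = image$plane)
}

#' First derivative of a line profile
#'
#' Central finite differences on the profile's own grid (one-sided at the
#' endpoints), with no smoothing.  Applied to an edge-spread function this
#' yields the line-spread function, whose width profiles the PSF.
#'
#' @param profile A [line_profile] with at least 3 samples.
#' @return A [line_profile] of the derivative (intensity per micrometer).
#' @export
differentiate <- function(profile) {
  stopifnot(inherits(profile, "line_profile"))
  y <- profile$intensities; x <- profile$positions
  n <- length(y)
  if (n < 3) stop_domain("profile must have at least 3 samples")
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  line_profile(x, d, plane = profile$plane)
}

#' Michelson contrast of a profile window
#'
#' `(Imax - Imin) / (Imax + Imin)` over the samples whose positions fall in
#' `feature_window`; the feature counts as resolved when the modulation
#' reaches `threshold`.
#'
#' @param profile A [line_profile].
#' @param feature_window Position range `c(lo, hi)` in the profile's units;
#'   `NULL` uses the whole profile.
#' @param threshold Modulation required to call the feature resolved.
#' @return An object of class `contrast_result`: list with `modulation`,
#'   `resolved`, `imax`, `imin`.
#' @export
feature_contrast <- function(profile, feature_window = NULL, threshold = 0.1) {
  stopifnot(inherits(profile, "line_profile"))
  y <- profile$intensities
  if (!is.null(feature_window)) {
    sel <- profile$positions >= feature_window[1] &
      profile$positions <= feature_window[2]
    if (!any(sel)) stop_domain("`feature_window` contains no profile samples")
    y <- y[sel]
  }
  imax <- max(y); imin <- min(y)
  modulation <- if (imax + imin > 0) (imax - imin) / (imax + imin) else 0
  structure(list(modulation = modulation, resolved = modulation >= threshold,
                 imax = imax, imin = imin),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> modulation %.3f (%s)\n", x$modulation,
              if (x$resolved) "resolved" else "not resolved"))
  invisible(x)
}
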