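#' Raster image container
#'
#' A minimal container for a grayscale (matrix) or RGB (3-slice array)
#' intensity raster together with the physical pixel pitch of the plane it
#' lives in.  Intensities are stored as doubles, conventionally in `[0, 1]`;
#' quantization to 8 or 16 bits happens only on file output.
#'
#' Coordinates throughout the package are 0-based with pixel centers at
#' integer coordinates, ordered (row, col).
#'
#' @param intensities Numeric matrix (grayscale) or rows x cols x 3 array
#'   (RGB) of finite, non-negative values.
#' @param pixel_pitch Physical center-to-center pixel spacing in micrometers,
#'   in the plane named by `plane`.
#' @param bit_depth One of `"float"`, `8`, `16`; the intended quantization on
#'   output.  Stored values are doubles regardless.
#' @param plane `"sensor"` or `"sample"`: the plane whose micrometers
#'   `pixel_pitch` measures.
#' @return An object of class `raster_image`.
#' @export
raster_image <- function(intensities, pixel_pitch, bit_depth = "float",
                         plane = c("sensor", "sample")) {
  plane <- match.arg(plane)
  if (!(is.matrix(intensities) ||
        (is.array(intensities) && length(dim(intensities)) == 3 &&
         dim(intensities)[3] == 3))) {
    stop_domain("`intensities` must be a matrix or a rows x cols x 3 array")
  }
  if (!all(is.finite(intensities))) {
    stop_domain("image intensities must all be finite")
  }
  if (any(intensities < 0)) {
    stop_domain("image intensities must be non-negative")
  }
  check_positive_scalar(pixel_pitch, "pixel_pitch")
  bd <- as.character(bit_depth)
  if (!bd %in% c("float", "8", "16")) {
    stop_domain("`bit_depth` must be \"float\", 8 or 16")
  }
  structure(
    list(intensities = intensities, pixel_pitch = pixel_pitch,
         bit_depth = bd, plane = plane),
    class = "raster_image"
  )
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$intensities)
  kind <- if (length(d) == 3) "RGB" else "grayscale"
  cat(sprintf("<raster_image> %d x %d %s, %.4g um/px (%s plane), bit depth %s\n",
              d[1], d[2], kind, x$pixel_pitch, x$plane, x$bit_depth))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' @export
dim.raster_image <- function(x) dim(x$intensities)

#' Convert an image to single-channel luminance
#'
#' RGB rasters are reduced to the per-pixel mean of the three channels before
#' any quantitative analysis; grayscale images pass through unchanged.
#'
#' @param image A [raster_image].
#' @return A grayscale [raster_image].
#' @export
as_grayscale <- function(image) {
  stopifnot(inherits(image, "raster_image"))
  v <- image$intensities
  if (is.matrix(v)) return(image)
  g <- (v[, , 1] + v[, , 2] + v[, , 3]) / 3
  raster_image(g, image$pixel_pitch, image$bit_depth, image$plane)
}

#' Read a TIFF or PNG image
#'
#' @param path File path; format chosen by extension (`.tif`, `.tiff`,
#'   `.png`).
#' @param pixel_pitch Pixel pitch in micrometers to attach (image files carry
#'   no physical scale).
#' @param plane Plane of `pixel_pitch`; see [raster_image].
#' @return A [raster_image] with intensities in `[0, 1]`.
#' @export
read_image <- function(path, pixel_pitch, plane = "sensor") {
  ext <- tolower(tools::file_ext(path))
  v <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop_domain(sprintf("unsupported image extension '%s'", ext))
  )
  if (is.array(v) && length(dim(v)) == 3 && dim(v)[3] == 4) {
    v <- v[, , 1:3]  # drop alpha
  }
  raster_image(v, pixel_pitch, bit_depth = "float", plane = plane)
}

#' Write an image as 16-bit TIFF or 8-bit PNG
#'
#' Values are clamped to `[0, 1]` and quantized.  TIFF output is 16-bit
#' grayscale by default; PNG output is 8-bit.
#'
#' @param image A [raster_image].
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "raster_image"))
  v <- pmin(pmax(image$intensities, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = ,
    tiff = tiff::writeTIFF(v, path, bits.per.sample = 16L),
    png = png::writePNG(v, path),
    stop_domain(sprintf("unsupported image extension '%s'", ext))
  )
  invisible(path)
}
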