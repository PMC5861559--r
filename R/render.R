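#' Grid distortion target specification
#'
#' A periodic square grid of chrome lines (dark) on glass (bright), the
#' standard target for measuring magnification and geometric distortion.
#' Typical commercial targets have 500 um or 100 um periods.
#'
#' @param period Center-to-center line spacing in micrometers.
#' @param line_width Line width in micrometers (must be less than `period`).
#' @param bar_intensity Line intensity in `[0, 1]`.
#' @param background_intensity Background intensity in `[0, 1]`.
#' @return An object of class `grid_target_spec`.
#' @export
grid_target_spec <- function(period = 500, line_width = 50,
                             bar_intensity = 0.1,
                             background_intensity = 0.95) {
  check_positive_scalar(period, "period")
  check_positive_scalar(line_width, "line_width")
  if (line_width >= period) {
    stop_domain("`line_width` must be smaller than `period`")
  }
  for (v in c(bar_intensity, background_intensity)) {
    if (!is_scalar_number(v) || v < 0 || v > 1) {
      stop_domain("intensities must be in [0, 1]")
    }
  }
  if (bar_intensity == background_intensity) {
    stop_domain("`bar_intensity` must differ from `background_intensity`")
  }
  structure(list(period = period, line_width = line_width,
                 bar_intensity = bar_intensity,
                 background_intensity = background_intensity),
            class = "grid_target_spec")
}

## Total length of [lo, hi] covered by periodic bars of width w centered at
## integer multiples of p.  Exact (no sampling); vectorized over lo/hi.
coverage_periodic <- function(lo, hi, p, w) {
  cum <- function(t) {
    u <- t + w / 2
    k <- floor(u / p)
    w * k + pmin(u - p * k, w)
  }
  (cum(hi) - cum(lo)) / (hi - lo)
}

## Fraction of [lo, hi] covered by the single interval [b0, b1]; vectorized.
coverage_interval <- function(lo, hi, b0, b1) {
  pmax(0, pmin(hi, b1) - pmax(lo, b0)) / (hi - lo)
}

## Sample-plane coordinates of sensor pixel centers (0-based index i along an
## axis of n pixels): x = (i - (n-1)/2) * pixel_pitch / M.  Returns the pixel
## aperture edges [lo, hi] in sample micrometers.
sample_plane_edges <- function(n, pixel_pitch, magnification) {
  a <- pixel_pitch / magnification
  centers <- ((0:(n - 1)) - (n - 1) / 2) * a
  list(lo = centers - a / 2, hi = centers + a / 2, centers = centers, a = a)
}

## Build the ideal (pre-blur, pre-noise) sensor-grid image of a pattern whose
## column/row coverages are given; returns a raster_image on the sample plane
## (pitch pixel_pitch / M) so apply_optics resamples it by exactly 1.
ideal_raster <- function(intensities, scene) {
  raster_image(intensities, scene$pixel_pitch / scene$magnification,
               bit_depth = "float", plane = "sample")
}

#' Render a grid distortion target
#'
#' Renders the ideal grid analytically on the sensor grid — each pixel value
#' is the exact area fraction of the pixel footprint covered by grid lines,
#' so edge positions carry sub-pixel information — and then applies the full
#' optics chain of the scene via [apply_optics].  A grid intersection falls
#' on the image center.
#'
#' @param spec A [grid_target_spec].
#' @param scene A [scene_config].
#' @return A [raster_image] on the sensor plane.
#' @export
render_grid <- function(spec, scene) {
  stopifnot(inherits(spec, "grid_target_spec"), inherits(scene, "scene_config"))
  nr <- scene$image_size[1]; nc <- scene$image_size[2]
  field_um <- min(nr, nc) * scene$pixel_pitch / scene$magnification
  if (field_um < spec$period) {
    stop_degenerate(sprintf(
      "field of view (%.1f um) is smaller than one grid period (%g um)",
      field_um, spec$period))
  }
  ex <- sample_plane_edges(nc, scene$pixel_pitch, scene$magnification)
  ey <- sample_plane_edges(nr, scene$pixel_pitch, scene$magnification)
  cx <- coverage_periodic(ex$lo, ex$hi, spec$period, spec$line_width)
  cy <- coverage_periodic(ey$lo, ey$hi, spec$period, spec$line_width)
  ## union coverage of the two orthogonal line families
  u <- 1 - outer(1 - cy, 1 - cx)
  img <- spec$background_intensity +
    (spec$bar_intensity - spec$background_intensity) * u
  apply_optics(ideal_raster(img, scene), scene)
}

#' Render USAF 1951 chart elements
#'
#' Renders three-bar elements of the requested groups in both orientations,
#' laid out on a regular synthetic raster (one column per group and
#' orientation; this layout is *not* the nested spiral of the physical
#' chart), with exact pixel-aperture integration, then applies the scene
#' optics.  Bars are dark on a bright background, with the standard 5:1
#' bar length-to-width ratio and gaps equal to the bar width.
#'
#' Alongside the image, a coordinate map gives a pixel-space bounding box for
#' every rendered element.  Boxes are 0-based, half-open `[r0, r1) x [c0, c1)`
#' and include a margin of 1.5 bar widths on every side so a cross-section
#' through the box captures the full outer edge transitions.
#'
#' @param scene A [scene_config].
#' @param groups Integer vector of chart groups to render.
#' @param elements Elements within each group (subset of 1:6).
#' @param orientations Bar orientations to render; `"vertical"` bars run along
#'   image rows (a horizontal cross-section crosses them), `"horizontal"` the
#'   converse.
#' @param bar_intensity,background_intensity Chrome and glass intensities.
#' @return An object of class `usaf_render`: a list with `image` (the
#'   [raster_image]), `elements` (the coordinate map data.frame with columns
#'   `group, element, orientation, resolution_lpmm, bar_width_um,
#'   bar_width_px, r0, c0, r1, c1`), and `scene`.
#' @export
render_usaf <- function(scene, groups, elements = 1:6,
                        orientations = c("vertical", "horizontal"),
                        bar_intensity = 0.1, background_intensity = 0.95) {
  stopifnot(inherits(scene, "scene_config"))
  orientations <- match.arg(orientations, c("vertical", "horizontal"),
                            several.ok = TRUE)
  nr <- scene$image_size[1]; nc <- scene$image_size[2]
  M <- scene$magnification; pp <- scene$pixel_pitch

  ## Lay out columns in sample-plane micrometers.  One column per
  ## (group, orientation); elements stacked within a column, coarsest first.
  cols <- expand.grid(orientation = orientations, group = sort(groups),
                      stringsAsFactors = FALSE)
  rects <- list()          # dark rectangles: (x0, x1, y0, y1) sample um
  map <- list()
  x_cursor <- 0
  for (ci in seq_len(nrow(cols))) {
    g <- cols$group[ci]; o <- cols$orientation[ci]
    spec <- usaf_bar_width(g, sort(elements))
    w_max <- max(spec$bar_width_um)
    y_cursor <- 0
    col_w <- 0
    for (ei in seq_len(nrow(spec))) {
      w <- spec$bar_width_um[ei]
      w_px <- w * M / pp
      if (w_px < 1) {
        warning(sprintf(
          "USAF group %d element %d: bar width %.3g px < 1 sensor pixel; skipped",
          g, spec$element[ei], w_px), call. = FALSE)
        next
      }
      ext <- 5 * w  # element is 5w x 5w in both orientations
      x0 <- x_cursor; y0 <- y_cursor
      for (k in 0:2) {
        if (o == "vertical") {
          rects[[length(rects) + 1]] <-
            c(x0 + 2 * k * w, x0 + (2 * k + 1) * w, y0, y0 + ext)
        } else {
          rects[[length(rects) + 1]] <-
            c(x0, x0 + ext, y0 + 2 * k * w, y0 + (2 * k + 1) * w)
        }
      }
      map[[length(map) + 1]] <- data.frame(
        group = g, element = spec$element[ei], orientation = o,
        resolution_lpmm = spec$resolution_lpmm[ei], bar_width_um = w,
        bar_width_px = w_px,
        x0 = x0 - 1.5 * w, x1 = x0 + ext + 1.5 * w,
        y0 = y0 - 1.5 * w, y1 = y0 + ext + 1.5 * w)
      y_cursor <- y_cursor + ext + 4 * w
      col_w <- max(col_w, ext)
    }
    x_cursor <- x_cursor + col_w + 4 * w_max
  }
  if (!length(map)) stop_degenerate("no USAF element is renderable at this scale")
  map <- do.call(rbind, map)

  ## center the layout on the optical axis
  xr <- range(c(map$x0, map$x1)); yr <- range(c(map$y0, map$y1))
  dx <- -mean(xr); dy <- -mean(yr)
  map$x0 <- map$x0 + dx; map$x1 <- map$x1 + dx
  map$y0 <- map$y0 + dy; map$y1 <- map$y1 + dy
  rects <- lapply(rects, function(r) r + c(dx, dx, dy, dy))

  ex <- sample_plane_edges(nc, pp, M)
  ey <- sample_plane_edges(nr, pp, M)
  img <- matrix(background_intensity, nr, nc)
  depth <- background_intensity - bar_intensity
  for (r in rects) {
    covx <- coverage_interval(ex$lo, ex$hi, r[1], r[2])
    covy <- coverage_interval(ey$lo, ey$hi, r[3], r[4])
    jx <- which(covx > 0); jy <- which(covy > 0)
    if (length(jx) && length(jy)) {
      img[jy, jx] <- img[jy, jx] - depth * outer(covy[jy], covx[jx])
    }
  }

  ## sample um -> 0-based pixel coordinates
  px_c <- function(x) x * M / pp + (nc - 1) / 2
  px_r <- function(y) y * M / pp + (nr - 1) / 2
  box <- data.frame(
    r0 = floor(px_r(map$y0)), c0 = floor(px_c(map$x0)),
    r1 = floor(px_r(map$y1)) + 1, c1 = floor(px_c(map$x1)) + 1)
  if (any(box$r0 < 0 | box$c0 < 0 | box$r1 > nr | box$c1 > nc)) {
    stop_degenerate("USAF layout does not fit in the image at this magnification")
  }
  out_map <- cbind(
    map[, c("group", "element", "orientation", "resolution_lpmm",
            "bar_width_um", "bar_width_px")],
    box)

  structure(list(image = apply_optics(ideal_raster(img, scene), scene),
                 elements = out_map, scene = scene),
            class = "usaf_render")
}

#' @export
print.usaf_render <- function(x, ...) {
  cat(sprintf("<usaf_render> %d element(s)\n", nrow(x$elements)))
  print(x$image)
  print(utils::head(x$elements, 12))
  invisible(x)
}

#' Write or read a USAF element coordinate map
#'
#' The coordinate map (pixel-space bounding boxes per group/element/
#' orientation) is serialized as a JSON array of records.
#'
#' @param map The `elements` data.frame of a [render_usaf] result.
#' @param path JSON file path.
#' @return `write_element_map` returns `path` invisibly; `read_element_map`
#'   returns the data.frame.
#' @export
write_element_map <- function(map, path) {
  jsonlite::write_json(map, path, dataframe = "rows", digits = NA)
  invisible(path)
}

#' @rdname write_element_map
#' @export
read_element_map <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Render a filament phantom
#'
#' Dark parallel filaments (e.g. insect-wing hairs, typically 6-7 um wide) on
#' a bright background, used to test whether fine features survive a given
#' PSF with measurable contrast.  Filaments run along image rows; a
#' horizontal cross-section crosses all of them.
#'
#' @param scene A [scene_config].
#' @param filament_width Filament width in sample-plane micrometers.
#' @param spacing Center-to-center filament spacing in micrometers.
#' @param n_filaments Number of filaments (0 gives a uniform background).
#' @param bar_intensity,background_intensity Filament and background
#'   intensities.
#' @return A [raster_image] on the sensor plane.
#' @export
add_filament_phantom <- function(scene, filament_width, spacing,
                                 n_filaments = 5, bar_intensity = 0.1,
                                 background_intensity = 0.95) {
  stopifnot(inherits(scene, "scene_config"))
  check_positive_scalar(filament_width, "filament_width")
  check_positive_scalar(spacing, "spacing")
  nr <- scene$image_size[1]; nc <- scene$image_size[2]
  ex <- sample_plane_edges(nc, scene$pixel_pitch, scene$magnification)
  covx <- numeric(nc)
  if (n_filaments > 0) {
    centers <- (seq_len(n_filaments) - 1 - (n_filaments - 1) / 2) * spacing
    for (cen in centers) {
      covx <- covx + coverage_interval(ex$lo, ex$hi,
                                       cen - filament_width / 2,
                                       cen + filament_width / 2)
    }
    covx <- pmin(covx, 1)
  }
  row_int <- background_intensity +
    (bar_intensity - background_intensity) * covx
  img <- matrix(row_int, nr, nc, byrow = TRUE)
  apply_optics(ideal_raster(img, scene), scene)
}
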