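#' Characterize one lens from its calibration-target images
#'
#' Runs the full per-lens pipeline: magnification (both axes) from the grid
#' distortion target, PSF width from edge derivatives of a USAF element
#' (converted to the sample plane with the measured magnification), Nyquist
#' sampling adequacy, optionally radial distortion, and — when a lens
#' specification with a numerical aperture is supplied — the
#' Rayleigh-criterion prediction at the configured wavelength.
#'
#' Any stage that fails is recorded in `notes` and the report is marked
#' partial rather than erroring; in particular, without a grid image the
#' resolution is reported in sensor-plane units.
#'
#' @param usaf A [render_usaf] result, or a sensor-plane [raster_image] of a
#'   USAF chart (then `element_map` is required).
#' @param grid_image A sensor-plane [raster_image] of the grid target, or
#'   `NULL`.
#' @param lens Optional [lens_spec] row for this lens.
#' @param element_map Coordinate map when `usaf` is a plain image.
#' @param known_period Grid target period in micrometers.
#' @param pixel_pitch Sensor pixel pitch in micrometers (defaults to the USAF
#'   image metadata).
#' @param group,element,orientation Which chart element to measure; defaults
#'   to the mapped element whose bar width is closest to 27.84 um (group 4,
#'   element 2), the conventional mid-scale choice.
#' @param wavelength Wavelength in nanometers for the Rayleigh prediction.
#' @param required_points Nyquist points-per-peak rule.
#' @param with_distortion Also fit radial distortion from the grid image.
#' @param ... Further arguments passed to [measure_resolution].
#' @return An object of class `lens_report`.
#' @export
characterize_lens <- function(usaf, grid_image = NULL, lens = NULL,
                              element_map = NULL, known_period = 500,
                              pixel_pitch = NULL, group = NULL,
                              element = NULL, orientation = NULL,
                              wavelength = 550, required_points = 7,
                              with_distortion = FALSE, ...) {
  if (inherits(usaf, "usaf_render")) {
    usaf_image <- usaf$image
    if (is.null(element_map)) element_map <- usaf$elements
  } else {
    usaf_image <- usaf
  }
  stopifnot(inherits(usaf_image, "raster_image"), is.data.frame(element_map))
  if (is.null(pixel_pitch)) pixel_pitch <- usaf_image$pixel_pitch
  if (!is.null(grid_image) &&
      abs(grid_image$pixel_pitch - pixel_pitch) > 1e-9) {
    stop_domain("grid and USAF images must share the same pixel pitch")
  }

  notes <- character(0)
  partial <- FALSE
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      notes <<- c(notes, sprintf("%s failed: %s", name, conditionMessage(e)))
      partial <<- TRUE
      NULL
    })
  }

  mag <- NULL
  if (is.null(grid_image)) {
    warning("no grid image supplied; resolution will be in sensor-plane units",
            call. = FALSE)
    notes <- c(notes, "no grid image: magnification not measured")
    partial <- TRUE
  } else {
    mag <- run_stage("magnification",
                     estimate_magnification(grid_image, known_period, pixel_pitch))
  }
  M <- if (is.null(mag)) NA_real_ else mean(c(mag$mx, mag$my))

  row <- pick_element(element_map, group, element, orientation)
  resolution <- run_stage("resolution", suppressWarnings(
    measure_resolution(usaf_image, row, magnification = M,
                       pixel_pitch = pixel_pitch,
                       required_points = required_points, ...)))

  distortion <- NULL
  if (with_distortion && !is.null(grid_image)) {
    distortion <- run_stage("distortion",
                            estimate_distortion(grid_image, known_period, pixel_pitch))
  }

  rayleigh_um <- NA_real_
  if (!is.null(lens) && is.finite(lens$na)) {
    rayleigh_um <- rayleigh_resolution(wavelength, lens$na) / 1000
  }

  config <- list(known_period = known_period, pixel_pitch = pixel_pitch,
                 wavelength = wavelength, required_points = required_points,
                 group = row$group, element = row$element,
                 orientation = row$orientation,
                 with_distortion = with_distortion)
  structure(
    list(lens = lens, magnification = mag, resolution = resolution,
         distortion = distortion, theoretical_resolution_um = rayleigh_um,
         working_distance = if (is.null(lens)) NA_real_ else lens$working_distance,
         cost = if (is.null(lens)) NA_real_ else lens$cost,
         partial = partial, notes = notes,
         config = config, config_hash = config_hash(config)),
    class = "lens_report")
}

pick_element <- function(map, group, element, orientation) {
  sel <- rep(TRUE, nrow(map))
  if (!is.null(group)) sel <- sel & map$group == group
  if (!is.null(element)) sel <- sel & map$element == element
  if (!is.null(orientation)) sel <- sel & map$orientation == orientation
  cand <- map[sel, , drop = FALSE]
  if (!nrow(cand)) stop_domain("requested element is not in the coordinate map")
  cand[which.min(abs(cand$bar_width_um - 27.84)), , drop = FALSE]
}

#' @export
print.lens_report <- function(x, ...) {
  name <- if (is.null(x$lens)) "(unnamed lens)" else x$lens$name
  cat(sprintf("<lens_report> %s%s  [config %s]\n", name,
              if (x$partial) " (partial)" else "", x$config_hash))
  if (!is.null(x$magnification)) {
    cat(sprintf("  magnification: %.3f x / %.3f y\n",
                x$magnification$mx, x$magnification$my))
  }
  if (!is.null(x$resolution)) {
    cat(sprintf("  resolution: %.3g +/- %.3g um FWHM (%s plane), %s\n",
                x$resolution$fwhm_mean, x$resolution$fwhm_sd,
                x$resolution$plane,
                if (isTRUE(x$resolution$adequate_sampling)) {
                  sprintf("%.1f points/peak (adequate)", x$resolution$points_per_peak)
                } else if (is.finite(x$resolution$points_per_peak)) {
                  sprintf("%.1f points/peak (undersampled)", x$resolution$points_per_peak)
                } else "sampling not assessed"))
  }
  if (!is.null(x$distortion)) {
    cat(sprintf("  distortion: k1 %.4g\n", x$distortion$k1))
  }
  if (is.finite(x$theoretical_resolution_um)) {
    cat(sprintf("  Rayleigh prediction: %.3g um at %g nm\n",
                x$theoretical_resolution_um, x$config$wavelength))
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Aggregate lens reports into a comparison table
#'
#' One row per lens with the measured magnification, resolution (mean and SD
#' of the fitted FWHMs), sampling adequacy, and the specification-sheet
#' working distance and cost.  No winner is chosen: lens selection balances
#' these columns against field of view and usability, which is a judgment
#' call.
#'
#' @param reports A list of [characterize_lens] results.
#' @param sort_by Column to sort by (default `"name"`).
#' @param decreasing Sort order.
#' @return A data.frame with one row per report.
#' @export
compare_lenses <- function(reports, sort_by = "name", decreasing = FALSE) {
  if (inherits(reports, "lens_report")) reports <- list(reports)
  stopifnot(length(reports) >= 1)
  rows <- lapply(reports, function(r) {
    data.frame(
      name = if (is.null(r$lens)) NA_character_ else r$lens$name,
      magnification = if (is.null(r$magnification)) NA_real_ else
        mean(c(r$magnification$mx, r$magnification$my)),
      resolution_um = if (is.null(r$resolution)) NA_real_ else r$resolution$fwhm_mean,
      resolution_sd_um = if (is.null(r$resolution)) NA_real_ else r$resolution$fwhm_sd,
      points_per_peak = if (is.null(r$resolution)) NA_real_ else r$resolution$points_per_peak,
      adequate_sampling = if (is.null(r$resolution)) NA else r$resolution$adequate_sampling,
      rayleigh_um = r$theoretical_resolution_um,
      working_distance_mm = r$working_distance,
      cost = r$cost,
      partial = r$partial,
      config_hash = r$config_hash,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!sort_by %in% names(out)) stop_domain(sprintf("unknown sort column '%s'", sort_by))
  out <- out[order(out[[sort_by]], decreasing = decreasing), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a lens report or comparison table
#'
#' Reports serialize as JSON (deterministically: no timestamps are stored, so
#' identical inputs and configuration give byte-identical files); comparison
#' tables as CSV or JSON.
#'
#' @param report A [characterize_lens] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lens_report <- function(report, path) {
  stopifnot(inherits(report, "lens_report"))
  x <- unclass(report)
  x$resolution$fit <- NULL  # drop the bulky fit object; peaks table remains
  x <- lapply(x, function(v) if (is.object(v)) unclass(v) else v)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null", na = "null")
  invisible(path)
}

#' @rdname write_lens_report
#' @param table A [compare_lenses] data.frame.
#' @param format `"csv"` or `"json"`.
#' @export
write_comparison <- function(table, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(table, path, row.names = FALSE)
  } else {
    jsonlite::write_json(table, path, dataframe = "rows", digits = NA,
                         na = "null")
  }
  invisible(path)
}
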