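#' Rayleigh-criterion resolution limit
#'
#' Minimum resolvable separation for an aberration-free lens,
#' `delta = 0.61 * lambda / NA`.  Units follow `wavelength`: pass nanometers,
#' get nanometers.
#'
#' @param wavelength Wavelength of the imaged light (>= 0).
#' @param na Numerical aperture (> 0).
#' @return Resolvable separation, same units as `wavelength`.  Vectorized.
#' @examples
#' rayleigh_resolution(550, 0.4)   # ~839 nm
#' @export
rayleigh_resolution <- function(wavelength, na) {
  if (!is.numeric(na) || any(!is.finite(na)) || any(na <= 0)) {
    stop_domain("`na` must be positive")
  }
  if (!is.numeric(wavelength) || any(!is.finite(wavelength)) || any(wavelength < 0)) {
    stop_domain("`wavelength` must be non-negative")
  }
  0.61 * wavelength / na
}

#' USAF 1951 element geometry
#'
#' The chart's resolution in line pairs per millimeter is
#' `2^(group + (element - 1) / 6)`; one line pair is a bar plus an equal gap,
#' so the bar width in micrometers is `500 / resolution`.
#'
#' @param group Integer group number (may be negative).
#' @param element Element number within the group, 1 to 6.
#' @return A data.frame with columns `group`, `element`, `resolution_lpmm`
#'   and `bar_width_um`.  Vectorized over both arguments.
#' @examples
#' usaf_bar_width(4, 2)   # 27.84 um bars
#' @export
usaf_bar_width <- function(group, element) {
  if (!is.numeric(element) || any(!is.finite(element)) ||
      any(element < 1) || any(element > 6) || any(element != round(element))) {
    stop_domain("`element` must be an integer between 1 and 6")
  }
  if (!is.numeric(group) || any(!is.finite(group)) || any(group != round(group))) {
    stop_domain("`group` must be an integer")
  }
  res <- 2 ^ (group + (element - 1) / 6)
  data.frame(group = group, element = element,
             resolution_lpmm = res, bar_width_um = 500 / res)
}

#' Nyquist sampling adequacy of the PSF
#'
#' Counts how many sensor pixels fall across the central peak of the point
#' spread function and compares against a required minimum (the conventional
#' rule of thumb is roughly 7 points across an in-focus peak).  The central
#' peak support is taken as `peak_support` times the FWHM; the default of 2
#' spans the peak down to ~6% of its height.
#'
#' @param fwhm_sample PSF full width at half maximum in sample-plane
#'   micrometers.
#' @param magnification Sample-to-sensor magnification M.
#' @param pixel_pitch Sensor pixel pitch in micrometers.
#' @param required_points Minimum points across the peak deemed adequate.
#' @param peak_support Peak support in units of FWHM (default 2).
#' @return A list with `points_per_peak` (real) and `adequate` (logical).
#' @examples
#' sampling_assessment(3.2, 1.2, 1.2)  # 6.4 points per peak
#' @export
sampling_assessment <- function(fwhm_sample, magnification, pixel_pitch,
                                required_points = 7, peak_support = 2) {
  check_positive_scalar(fwhm_sample, "fwhm_sample")
  check_positive_scalar(magnification, "magnification")
  check_positive_scalar(pixel_pitch, "pixel_pitch")
  check_positive_scalar(required_points, "required_points")
  check_positive_scalar(peak_support, "peak_support")
  pts <- peak_support * fwhm_sample * magnification / pixel_pitch
  list(points_per_peak = pts, adequate = pts >= required_points)
}

#' Lens specification record
#'
#' @param name Lens model name.
#' @param supplier Supplier name.
#' @param cost Cost per unit (currency units).
#' @param material Lens material.
#' @param na Numerical aperture, in (0, 1) for lenses in air.
#' @param focal_length Focal length in mm.
#' @param working_distance Working distance in mm.
#' @param diameter Physical diameter in mm.
#' @param clear_aperture Clear aperture in mm.
#' @return An object of class `lens_spec` (a one-row data.frame).
#' @export
lens_spec <- function(name, supplier = NA_character_, cost = NA_real_,
                      material = NA_character_, na = NA_real_,
                      focal_length = NA_real_, working_distance = NA_real_,
                      diameter = NA_real_, clear_aperture = NA_real_) {
  if (!is.na(na) && (na <= 0 || na >= 1)) {
    stop_domain("`na` must be in (0, 1) for a lens in air")
  }
  out <- data.frame(name = name, supplier = supplier, cost = cost,
                    material = material, na = na,
                    focal_length = focal_length,
                    working_distance = working_distance,
                    diameter = diameter, clear_aperture = clear_aperture,
                    stringsAsFactors = FALSE)
  class(out) <- c("lens_spec", "data.frame")
  out
}

## Canonical supplier-table headers and their internal names.
.lens_table_headers <- c(
  "Lens" = "name", "Supplier" = "supplier", "Cost ($)" = "cost",
  "Material" = "material", "NA" = "na", "Focal length (mm)" = "focal_length",
  "Working distance (mm)" = "working_distance", "Diameter (mm)" = "diameter",
  "Clear aperture (mm)" = "clear_aperture"
)

#' Read a lens specification table
#'
#' Reads a CSV (or JSON array of records) whose columns follow the supplier
#' table convention: `Lens, Supplier, Cost ($), Material, NA,
#' Focal length (mm), Working distance (mm), Diameter (mm),
#' Clear aperture (mm)`.  A bundled example table of five candidate aspheric
#' lenses ships in `inst/extdata/lenses.csv`.
#'
#' @param path CSV or JSON file path.
#' @return A data.frame of class `lens_spec`, one row per lens.
#' @examples
#' lenses <- read_lens_table(system.file("extdata", "lenses.csv",
#'                                       package = "lenschar"))
#' @export
read_lens_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  } else {
    raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  }
  missing <- setdiff(names(.lens_table_headers), names(raw))
  if (length(missing)) {
    ## tolerate already-clean internal names
    if (all(.lens_table_headers %in% names(raw))) {
      out <- raw[, .lens_table_headers]
    } else {
      stop_domain(paste0("lens table is missing columns: ",
                         paste(missing, collapse = ", ")))
    }
  } else {
    out <- raw[, names(.lens_table_headers)]
    names(out) <- .lens_table_headers
  }
  ## costs may be printed as "<1"; parse the bound's value
  if (is.character(out$cost)) {
    out$cost <- as.numeric(gsub("[^0-9.]", "", out$cost))
  }
  class(out) <- c("lens_spec", "data.frame")
  out
}
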