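test_that("identical scene configuration gives bit-identical renders", {
  a <- make_grid(M = 1, fwhm = 2, seed = 5, noise = 0.02, period = 100, size = 220)
  b <- make_grid(M = 1, fwhm = 2, seed = 5, noise = 0.02, period = 100, size = 220)
  expect_identical(a$intensities, b$intensities)
  # a different seed changes the noise realization
  c <- make_grid(M = 1, fwhm = 2, seed = 6, noise = 0.02, period = 100, size = 220)
  expect_false(identical(a$intensities, c$intensities))
  # rendering must not disturb the caller's RNG stream
  set.seed(42); before <- rnorm(1)
  set.seed(42); invisible(make_grid(period = 100, size = 160, noise = 0.01))
  expect_identical(rnorm(1), before)
})

test_that("noiseless grid line spacing equals period * M / pixel_pitch", {
  # 500 um period at M = 1 on a 1.2 um sensor: 416.67 px
  g <- make_grid(M = 1, period = 500, size = 1000)
  px <- estimate_grid_period(g, "x")
  expect_equal(px$period_px, 500 / 1.2, tolerance = 0.5 / (500 / 1.2))
  # M = 1.2: the factors cancel to 500 px
  g2 <- make_grid(M = 1.2, period = 500, size = 1200)
  expect_equal(estimate_grid_period(g2, "x")$period_px, 500,
               tolerance = 0.5 / 500)
})

test_that("degenerate scenes and invalid target specs error", {
  expect_error(grid_target_spec(100, 100), class = "lenschar_domain_error")
  expect_error(grid_target_spec(100, 10, bar_intensity = 0.5,
                                background_intensity = 0.5),
               class = "lenschar_domain_error")
  sc <- scene_config(image_size = c(64, 64))  # 76.8 um field < one period
  expect_error(render_grid(grid_target_spec(500, 50), sc),
               class = "lenschar_degenerate_scene")
})

test_that("apply_optics is the identity when every stage is disabled", {
  sc <- scene_config(magnification = 1, pixel_pitch = 1.2, psf_fwhm = 0,
                     image_size = c(120, 120))
  ideal <- raster_image(matrix(runif(120 * 120), 120), 1.2, plane = "sample")
  out <- apply_optics(ideal, sc)
  expect_identical(out$intensities, ideal$intensities)
})

test_that("blur conserves energy away from borders", {
  g0 <- make_grid(M = 1, fwhm = 0, period = 100, size = 400)
  g1 <- make_grid(M = 1, fwhm = 6, period = 100, size = 400)
  # window spanning 3 full periods with edges in flat background between
  # lines, so blur moves no flux across its boundary
  core <- 76:325
  expect_equal(mean(g1$intensities[core, core]),
               mean(g0$intensities[core, core]), tolerance = 1e-3)
})

test_that("pincushion distortion stretches the corner period beyond the center", {
  g <- make_grid(M = 1, fwhm = 1.5, k1 = 0.08, period = 100, size = 900)
  crop <- function(img, rows, cols) {
    raster_image(img$intensities[rows, cols], img$pixel_pitch, plane = img$plane)
  }
  n <- nrow(g$intensities)
  center <- estimate_grid_period(crop(g, (n/2 - 150):(n/2 + 150),
                                      (n/2 - 150):(n/2 + 150)), "x")$period_px
  corner <- estimate_grid_period(crop(g, 1:301, 1:301), "x")$period_px
  expect_gt(corner, center)
  # spacing grows monotonically with field radius: successive line gaps
  # measured outward from the center increase
  mid_row <- colMeans(g$intensities[(n/2 - 30):(n/2 + 30), ])
  centers <- sort(lenschar:::detect_line_centers(mid_row))
  right <- centers[centers > n / 2]
  expect_true(all(diff(diff(right)) > 0))
  # non-invertible mapping is refused
  expect_error(make_grid(k1 = -0.5, period = 100, size = 300),
               class = "lenschar_domain_error")
})

test_that("USAF render reports exact bar geometry and a usable element map", {
  u <- make_usaf42(M = 1)
  expect_equal(u$elements$bar_width_px, 27.84 / 1.2, tolerance = 2e-4)
  expect_equal(u$elements$resolution_lpmm, 2^(4 + 1 / 6), tolerance = 1e-10)
  # a cross-section through the mapped box crosses exactly 6 bar edges
  row <- u$elements[1, ]
  prof <- extract_profile(u$image, c((row$r0 + row$r1) / 2, row$c0),
                          c((row$r0 + row$r1) / 2, row$c1 - 1))
  y <- prof$intensities
  mid <- (max(y) + min(y)) / 2
  expect_equal(sum(diff(y > mid) != 0), 6)
  # map serialization round-trips
  path <- withr::local_tempfile(fileext = ".json")
  write_element_map(u$elements, path)
  back <- read_element_map(path)
  expect_equal(back$bar_width_um, u$elements$bar_width_um)
  expect_equal(back$r0, u$elements$r0)
})

test_that("sub-pixel USAF elements are skipped with a warning", {
  # at M = 0.31 a group-7 element-1 bar is just over one pixel but element 2
  # falls below it
  sc <- scene_config(magnification = 0.31, image_size = c(120, 120))
  expect_warning(
    u <- render_usaf(sc, groups = 7, elements = 1:2, orientations = "vertical"),
    "skipped")
  expect_equal(nrow(u$elements), 1)
  expect_equal(u$elements$element, 1)
})

test_that("filament phantom contrast falls with blur", {
  prof_for <- function(fwhm) {
    sc <- scene_config(magnification = 1, psf_fwhm = fwhm,
                       image_size = c(120, 220))
    img <- add_filament_phantom(sc, filament_width = 6, spacing = 25)
    extract_profile(img, c(60, 10), c(60, 209))
  }
  c3 <- feature_contrast(prof_for(3))
  c9 <- feature_contrast(prof_for(9))
  expect_gt(c3$modulation, 0.2)
  expect_lt(c9$modulation, c3$modulation)
  # zero filaments: uniform background
  sc <- scene_config(image_size = c(60, 60))
  flat <- add_filament_phantom(sc, 6, 25, n_filaments = 0)
  expect_equal(diff(range(flat$intensities)), 0)
})

test_that("scene configs round-trip through JSON and YAML", {
  sc <- scene_config(magnification = 1.2, psf_fwhm = 3.2, distortion_k1 = 0.02,
                     read_noise_sd = 0.017, seed = 9, image_size = c(300, 301))
  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_scene_config(sc, path)
    expect_equal(read_scene_config(path), sc)
  }
})

test_that("images round-trip through 16-bit TIFF and 8-bit PNG", {
  img <- make_grid(M = 1, period = 100, size = 160)
  tif <- withr::local_tempfile(fileext = ".tif")
  write_image(img, tif)
  back <- read_image(tif, pixel_pitch = 1.2)
  expect_equal(back$intensities, img$intensities, tolerance = 1 / 65535)
  png <- withr::local_tempfile(fileext = ".png")
  write_image(img, png)
  back8 <- read_image(png, pixel_pitch = 1.2)
  expect_equal(back8$intensities, img$intensities, tolerance = 1 / 255)
})
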