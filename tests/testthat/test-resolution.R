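test_that("a known PSF round-trips through the edge-derivative measurement", {
  u <- make_usaf42(M = 1.2, fwhm = 3.2, seed = 11, noise = SNR50_NOISE)
  r <- measure_resolution(u$image, u$elements[1, ], magnification = 1.2)
  expect_equal(r$fwhm_mean, 3.2, tolerance = 0.05)
  expect_equal(r$n_edges, 6)
  expect_equal(r$plane, "sample")
  expect_equal(r$points_per_peak, 2 * r$fwhm_mean * 1.2 / 1.2)
  # sensor-plane FWHM = sample-plane FWHM * M exactly, by construction
  expect_equal(r$peaks$fwhm_sensor_um, r$peaks$fwhm_um * 1.2)
})

test_that("blurrier optics always measure wider", {
  r3 <- measure_resolution(make_usaf42(M = 1, fwhm = 3, seed = 4)$image,
                           make_usaf42(M = 1, fwhm = 3, seed = 4)$elements[1, ],
                           magnification = 1)
  u9 <- make_usaf42(M = 1, fwhm = 9, seed = 4)
  r9 <- measure_resolution(u9$image, u9$elements[1, ], magnification = 1)
  expect_gt(r9$fwhm_mean, r3$fwhm_mean)
})

test_that("the estimate is invariant to intensity scaling and inversion", {
  u <- make_usaf42(M = 1, fwhm = 3.5, seed = 6, noise = SNR50_NOISE / 2)
  base <- measure_resolution(u$image, u$elements[1, ], magnification = 1)
  scaled <- raster_image(u$image$intensities * 0.4, 1.2)
  r_s <- measure_resolution(scaled, u$elements[1, ], magnification = 1)
  expect_equal(r_s$fwhm_mean, base$fwhm_mean, tolerance = 0.02)
  inverted <- raster_image(1.05 - u$image$intensities, 1.2)
  r_i <- measure_resolution(inverted, u$elements[1, ], magnification = 1)
  expect_equal(r_i$fwhm_mean, base$fwhm_mean, tolerance = 0.02)
})

test_that("orientation of the cross-section is auto-detected", {
  sc <- scene_config(magnification = 1, psf_fwhm = 3, image_size = c(280, 280))
  u <- render_usaf(sc, groups = 4, elements = 2, orientations = "horizontal")
  roi <- c(u$elements$r0[1], u$elements$c0[1], u$elements$r1[1], u$elements$c1[1])
  r <- measure_resolution(u$image, roi, magnification = 1)  # no orientation given
  expect_equal(r$n_edges, 6)
  expect_equal(r$fwhm_mean, 3, tolerance = 0.06)
})

test_that("missing magnification degrades to sensor-plane units with a warning", {
  u <- make_usaf42(M = 1, fwhm = 4, seed = 8)
  expect_warning(
    r <- measure_resolution(u$image, u$elements[1, ], magnification = NA),
    "sensor-plane")
  expect_equal(r$plane, "sensor")
  expect_true(is.na(r$points_per_peak))
})

test_that("smallest resolvable element tracks the blur", {
  chart <- function(fwhm) {
    sc <- scene_config(magnification = 1, psf_fwhm = fwhm,
                       image_size = c(480, 450))
    render_usaf(sc, groups = 4:5, elements = c(2, 5), orientations = "vertical")
  }
  sharp <- chart(0)
  fine <- smallest_resolvable_element(sharp)
  # with no blur the finest rendered element is resolvable
  expect_equal(fine$bar_width_um, min(sharp$elements$bar_width_um))
  blur3 <- smallest_resolvable_element(chart(3))
  blur9 <- smallest_resolvable_element(chart(9))
  expect_lte(blur3$bar_width_um, blur9$bar_width_um)
  # nothing survives a modulation threshold of 1 after blurring
  expect_null(smallest_resolvable_element(chart(3), modulation_threshold = 1))
})
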