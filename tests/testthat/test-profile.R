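test_that("horizontal cross-sections reproduce pixel rows exactly", {
  m <- matrix(runif(40 * 60), 40, 60)
  img <- raster_image(m, 1.2)
  prof <- extract_profile(img, c(12, 0), c(12, 59))
  expect_equal(prof$intensities, m[13, ])
  expect_equal(prof$positions, (0:59) * 1.2)
  expect_equal(prof$spacing, 1.2)
})

test_that("width averaging reduces independent noise by about sqrt(width)", {
  set.seed(31)
  m <- matrix(0.5 + rnorm(200 * 200, sd = 0.05), 200, 200)
  img <- raster_image(pmax(m, 0), 1.2)
  sds <- sapply(seq(20, 170, by = 10), function(r) {
    p1 <- extract_profile(img, c(r, 5), c(r, 194), width_px = 1)
    p5 <- extract_profile(img, c(r, 5), c(r, 194), width_px = 5)
    c(sd(p1$intensities), sd(p5$intensities))
  })
  ratio <- mean(sds[1, ]) / mean(sds[2, ])
  expect_equal(ratio, sqrt(5), tolerance = 0.15)
})

test_that("profiles outside the image raise geometry errors", {
  img <- raster_image(matrix(0.5, 30, 30), 1.2)
  expect_error(extract_profile(img, c(5, -2), c(5, 20)),
               class = "lenschar_geometry_error")
  expect_error(extract_profile(img, c(2, 2), c(2, 40)),
               class = "lenschar_geometry_error")
  # width offsets count too
  expect_error(extract_profile(img, c(0, 2), c(0, 27), width_px = 5),
               class = "lenschar_geometry_error")
})

test_that("differentiation is exact on ramps and localizes steps", {
  x <- (0:49) * 1.2
  ramp <- line_profile(x, 0.3 + 0.01 * x)
  d <- differentiate(ramp)
  expect_equal(d$intensities, rep(0.01, 50))
  step <- line_profile(x, as.numeric(x >= 30))
  ds <- differentiate(step)
  expect_equal(sum(ds$intensities != 0), 2)  # central differences straddle it
  expect_error(differentiate(line_profile(x[1:2], c(0, 1))),
               class = "lenschar_domain_error")
})

test_that("derivative of a Gaussian edge matches the analytic LSF", {
  # d/dx [step (x) Gaussian] = the same Gaussian; checked at fine sampling
  # for FWHM across the realistic PSF range
  for (fwhm in c(1, 3.2, 6, 12)) {
    prof <- analytic_edge_profile(fwhm, magnification = 1, refine = 12)
    d <- differentiate(prof)
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    x0 <- prof$positions[which.min(abs(prof$intensities - 0.5))]
    g <- dnorm(d$positions, mean = x0, sd = sigma)
    # align the analytic curve's center by least squares over a fine shift
    shifts <- seq(-prof$spacing, prof$spacing, length.out = 41)
    nrmse <- min(sapply(shifts, function(s) {
      gg <- dnorm(d$positions, mean = x0 + s, sd = sigma)
      sqrt(mean((d$intensities - gg)^2)) / max(gg)
    }))
    expect_lt(nrmse, 0.02)
  }
})

test_that("Michelson contrast behaves at the extremes", {
  x <- (0:99) * 1
  square <- line_profile(x, rep(c(1, 1, 0, 0), 25))
  expect_equal(feature_contrast(square)$modulation, 1)
  flat <- line_profile(x, rep(0.4, 100))
  fc <- feature_contrast(flat)
  expect_equal(fc$modulation, 0)
  expect_false(fc$resolved)
  expect_error(feature_contrast(flat, c(500, 600)),
               class = "lenschar_domain_error")
  # windowing restricts the measurement
  half <- line_profile(x, c(rep(0.5, 50), rep(c(0.2, 0.8), 25)))
  expect_equal(feature_contrast(half, c(0, 49))$modulation, 0)
  expect_gt(feature_contrast(half, c(50, 99))$modulation, 0.5)
})
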