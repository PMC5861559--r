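test_that("a noiseless single Gaussian is recovered essentially exactly", {
  x <- seq(0, 40, by = 0.4)
  truth <- c(amplitude = 1.7, center = 22.3, sigma = 2.1)
  y <- 0.05 + truth["amplitude"] * exp(-(x - truth["center"])^2 /
                                         (2 * truth["sigma"]^2))
  fit <- fit_multi_gaussian(line_profile(x, y))
  expect_equal(nrow(fit$peaks), 1)
  expect_equal(fit$peaks$amplitude, unname(truth["amplitude"]), tolerance = 1e-6)
  expect_equal(fit$peaks$center, unname(truth["center"]), tolerance = 1e-6)
  expect_equal(fit$peaks$sigma, unname(truth["sigma"]), tolerance = 1e-6)
  expect_equal(fit$baseline, 0.05, tolerance = 1e-6)
  expect_equal(fit$peaks$fwhm, 2 * sqrt(2 * log(2)) * fit$peaks$sigma)
})

test_that("opposite-sign peaks at SNR 50 are recovered within tight bounds", {
  set.seed(77)
  x <- seq(0, 60, by = 0.5)
  sig <- 2.4; sep <- 4 * sig
  c1 <- 30 - sep / 2; c2 <- 30 + sep / 2
  clean <- exp(-(x - c1)^2 / (2 * sig^2)) - exp(-(x - c2)^2 / (2 * sig^2))
  y <- clean + rnorm(length(x), sd = 1 / 50)
  fit <- fit_multi_gaussian(line_profile(x, y), expected_peaks = 2)
  expect_equal(fit$peaks$center, c(c1, c2), tolerance = 0.1 * sig / c1)
  expect_equal(fit$peaks$sigma, c(sig, sig), tolerance = 0.05)
  expect_equal(sign(fit$peaks$amplitude), c(1, -1))
})

test_that("a rendered 3-bar element yields 6 alternating-sign peaks", {
  u <- make_usaf42(M = 1, fwhm = 3, seed = 2, noise = SNR50_NOISE)
  row <- u$elements[1, ]
  prof <- extract_profile(u$image, c((row$r0 + row$r1) / 2, row$c0),
                          c((row$r0 + row$r1) / 2, row$c1 - 1))
  fit <- fit_multi_gaussian(differentiate(prof), expected_peaks = 6)
  expect_equal(nrow(fit$peaks), 6)
  expect_equal(sign(fit$peaks$amplitude), rep(c(-1, 1), 3))  # dark bars first
  # transitions sit one bar width apart
  expect_equal(diff(fit$peaks$center),
               rep(27.84, 5), tolerance = 0.05)
})

test_that("fit failures are typed errors", {
  x <- seq(0, 30, by = 0.5)
  set.seed(3)
  flat <- line_profile(x, rnorm(length(x), sd = 0.01))
  expect_error(fit_multi_gaussian(flat, expected_peaks = 4),
               class = "lenschar_fit_error")
})

test_that("the fit object supports the standard model-object verbs", {
  x <- seq(0, 30, by = 0.3)
  y <- 0.1 + 2 * exp(-(x - 14)^2 / (2 * 1.8^2))
  fit <- fit_multi_gaussian(line_profile(x, y))
  expect_named(coef(fit), c("baseline", "amplitude1", "center1", "sigma1"))
  expect_equal(fitted(fit), predict(fit))
  expect_equal(predict(fit, 14), 2.1, tolerance = 1e-5)
  expect_lt(max(abs(residuals(fit))), 1e-6)
  s <- summary(fit)
  expect_s3_class(s, "summary.multigauss_fit")
  expect_equal(s$fwhm_mean, fit$peaks$fwhm[1])
  expect_output(print(fit), "multigauss_fit")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
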