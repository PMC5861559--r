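lenses <- read_lens_table(system.file("extdata", "lenses.csv",
                                      package = "lenschar"))

make_report <- function(M = 1.2, fwhm = 3.2, seed = 21, lens = NULL,
                        with_distortion = FALSE, period = 500) {
  g <- make_grid(M = M, fwhm = fwhm, seed = seed, noise = SNR50_NOISE,
                 period = period)
  u <- make_usaf42(M = M, fwhm = fwhm, seed = seed + 1, noise = SNR50_NOISE)
  characterize_lens(u, grid_image = g, lens = lens, known_period = period,
                    with_distortion = with_distortion)
}

test_that("a full synthetic scene round-trips through characterize_lens", {
  rep <- make_report(M = 1.2, fwhm = 3.2,
                     lens = lenses[lenses$name == "CAY046", ])
  expect_false(rep$partial)
  expect_equal(mean(c(rep$magnification$mx, rep$magnification$my)), 1.2,
               tolerance = 0.02)
  expect_equal(rep$resolution$fwhm_mean, 3.2, tolerance = 0.05)
  expect_equal(rep$config$group, 4)
  expect_equal(rep$config$element, 2)
  # Rayleigh prediction from the lens NA at the default 550 nm, in um
  expect_equal(rep$theoretical_resolution_um, 0.61 * 0.550 / 0.4)
  expect_equal(rep$cost, 6)
  expect_equal(rep$working_distance, 3.0)
  expect_match(rep$config_hash, "^[0-9a-f]{8}$")
})

test_that("a missing grid image yields a partial sensor-plane report", {
  u <- make_usaf42(M = 1.2, fwhm = 3.2, seed = 31, noise = SNR50_NOISE)
  expect_warning(rep <- characterize_lens(u, grid_image = NULL), "grid")
  expect_true(rep$partial)
  expect_null(rep$magnification)
  expect_equal(rep$resolution$plane, "sensor")
  # sensor-plane width = sample width * M for this scene
  expect_equal(rep$resolution$fwhm_mean, 3.2 * 1.2, tolerance = 0.06)
  expect_true(any(grepl("magnification", rep$notes)))
})

test_that("comparison tables carry the per-lens summary columns and sort", {
  reps <- list(
    make_report(M = 1.2, fwhm = 3.2, seed = 41,
                lens = lenses[lenses$name == "CAY046", ]),
    make_report(M = 0.7, fwhm = 9.2, seed = 43,
                lens = lenses[lenses$name == "Budget", ]))
  tab <- compare_lenses(reps, sort_by = "resolution_um")
  expect_equal(nrow(tab), 2)
  expect_true(all(c("name", "magnification", "resolution_um",
                    "resolution_sd_um", "points_per_peak",
                    "working_distance_mm", "cost") %in% names(tab)))
  expect_equal(tab$name, c("CAY046", "Budget"))  # ascending resolution
  expect_false(is.unsorted(tab$resolution_um))
  # single report -> single-row table
  expect_equal(nrow(compare_lenses(reps[[1]])), 1)
  expect_error(compare_lenses(reps, sort_by = "nope"),
               class = "lenschar_domain_error")
})

test_that("reports are byte-identical when regenerated from the same inputs", {
  r1 <- make_report(seed = 51, with_distortion = TRUE, period = 100)
  r2 <- make_report(seed = 51, with_distortion = TRUE, period = 100)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_lens_report(r1, p1)
  write_lens_report(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_true(is.finite(r1$distortion$k1))
  # comparison table writers
  tab <- compare_lenses(list(r1))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_comparison(tab, csv)
  expect_equal(read.csv(csv)$resolution_um, tab$resolution_um)
})
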