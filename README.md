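# lenschar

Quantitative optical characterization of simple microscope objectives —
the single aspheric lenses used in smartphone microscopes and other
low-cost imaging systems — from photographs of two standard calibration
targets:

* a **grid distortion target** of known period, which yields the
  sample-to-sensor magnification along both axes and the radial
  (pincushion/barrel) distortion coefficient;
* a **USAF 1951 resolution chart**, whose chrome-on-glass bar edges are
  ideal steps: the first derivative of a cross-section through a chart
  element is the line-spread function, and fitting one signed Gaussian
  per edge transition measures the point-spread-function width directly.

It is intended for anyone who needs to compare candidate lenses on
measured numbers — magnification, PSF FWHM, sampling adequacy, working
distance, cost — rather than on specification sheets: instrument
builders, public-engagement and frugal-science projects, teaching labs.

## The measurements

**Rayleigh limit** (ideal resolution of an aberration-free lens):
`Δx = 0.61 λ / NA` — `rayleigh_resolution()`.

**Chart geometry**: USAF 1951 resolution in line pairs/mm is
`2^(group + (element − 1)/6)`; one bar is `500 / resolution` µm wide —
`usaf_bar_width()`. Element 4-2, the conventional mid-scale probe, has
27.84 µm bars.

**Magnification**: a grid of period `P` µm images to `P·M/p` pixels at
pixel pitch `p`; line centers are detected to sub-pixel precision in the
central field — `estimate_magnification()`.

**Resolution**: cross-section → first derivative (no smoothing) →
multi-peak Gaussian least squares; mean ± SD of the six transition
FWHMs, corrected for the pixel-aperture and derivative-kernel widths and
reported in sample-plane µm — `measure_resolution()`.

**Sampling**: `2·FWHM·M/p` sensor pixels across the central PSF peak,
compared with the ~7-point Nyquist rule of thumb —
`sampling_assessment()`.

**Distortion**: one-coefficient Brown model `r' = r(1 + k1 (r/Rn)²)`,
`k1 > 0` = pincushion — `estimate_distortion()`.

A forward renderer (`render_grid()`, `render_usaf()`,
`add_filament_phantom()`, `apply_optics()`) produces synthetic target
images with known ground truth — magnification, distortion, Gaussian or
Airy PSF, vignetting, Poisson + read noise, all seeded and bit-
reproducible — so the entire measurement chain is testable end to end.
See the vignette (`vignettes/lens-characterization.Rmd`) for the methods
in full.

## Worked example

Characterize a CAY046-like lens (M ≈ 1.2, PSF FWHM 3.2 µm) on a
1.2 µm-pitch sensor, entirely from synthetic scenes:

```r
library(lenschar)

scene <- scene_config(magnification = 1.2, pixel_pitch = 1.2, psf_fwhm = 3.2,
                      read_noise_sd = 0.017, seed = 7, image_size = c(1150, 1150))
grid <- render_grid(grid_target_spec(period = 500, line_width = 50), scene)
estimate_magnification(grid, known_period = 500)
#> <magnification_estimate> Mx 1.2000, My 1.2000 (periods 500.00 / 500.00 px, +/- 8.85e-06)

usc <- scene_config(magnification = 1.2, pixel_pitch = 1.2, psf_fwhm = 3.2,
                    read_noise_sd = 0.017, seed = 8, image_size = c(420, 420))
chart <- render_usaf(usc, groups = 4, elements = 2, orientations = "vertical")
measure_resolution(chart$image, chart$elements[1, ], magnification = 1.2)
#> <psf_estimate> FWHM 3.24 +/- 0.256 um (sample plane), 6 edges
#>   sampling: 6.49 points per peak (inadequate)

lenses <- read_lens_table(system.file("extdata", "lenses.csv", package = "lenschar"))
characterize_lens(chart, grid_image = grid,
                  lens = lenses[lenses$name == "CAY046", ])
#> <lens_report> CAY046  [config 472a6c0e]
#>   magnification: 1.200 x / 1.200 y
#>   resolution: 3.24 +/- 0.256 um FWHM (sample plane), 6.5 points/peak (undersampled)
#>   Rayleigh prediction: 0.839 um at 550 nm
```

Reading the numbers: the 500 µm grid imaged to 500.00 px spacing, so
M = 500 × 1.2 / 500 = 1.200 on both axes. The six edge derivatives of
element 4-2 fit to 3.24 ± 0.26 µm FWHM in the sample plane — within 2 %
of the 3.2 µm ground truth built into the scene. At M = 1.2 on 1.2 µm
pixels that peak spans 6.5 samples, just under the 7-point rule, and far
above the 0.84 µm Rayleigh prediction for NA 0.4 at 550 nm — the gap
between ideal and measured is exactly what separates a one-element
aspheric from a corrected objective. `compare_lenses()` stacks such
reports into a per-lens table; a thin command-line wrapper with
`simulate` / `magnify` / `resolve` / `characterize` / `compare`
subcommands lives at `inst/cli/lenschar.R`.

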