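---
title: "Measuring lens performance from calibration targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lens performance from calibration targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lenschar)
```

## The measurement problem

Simple single-lens microscopes — above all smartphone microscopes built
around one aspheric objective — are not limited by magnification but by
optical resolution and by whether the sensor samples that resolution
adequately. For an aberration-free lens the Rayleigh criterion sets the
ideal limit,

$$\Delta x = \frac{0.61\,\lambda}{\mathrm{NA}},$$

but real low-cost aspherics fall short of it through aberrations, focus
error and stray light, so the practical figure of merit is the *measured*
width of the point spread function (PSF). `lenschar` implements that
measurement from two standard calibration targets, plus everything needed
to validate it on synthetic scenes with known ground truth.

## Magnification from a grid target

A grid distortion target of known period $P$ (typically 500 µm or
100 µm) images to a line spacing of $P \cdot M / p$ sensor pixels, where
$M$ is the sample-to-sensor magnification and $p$ the pixel pitch.
`estimate_grid_period()` projects the image onto each axis and measures
the mean spacing of detected line centers; `estimate_magnification()`
inverts the relation per axis. Implementation choices that matter:

* Detection starts in the **central third** of the field, where radial
  distortion bias is smallest, and widens only if fewer than three lines
  are found there.
* Line centers are refined to sub-pixel precision: a three-point parabola
  through the projection extremum for narrow lines, and the weighted
  centroid of the above-threshold run for thick lines, whose flat-topped
  projection makes a parabola through the apex noise-dominated.
* Runs truncated by the window edge are discarded — their centroids are
  biased inward.
* RGB input is reduced to the mean of the channels before analysis.

On noiseless synthetic grids the recovered period is accurate to well
under half a pixel, and across the magnification range 0.5–1.5 with
edge signal-to-noise ratio 50 the recovered $M$ stays within 2 % of
ground truth.

## Resolution from USAF chart edges

The USAF 1951 chart is a binary chrome-on-glass pattern; its bar edges
are ideal step transitions. A cross-section through a three-bar element
is therefore a sum of edge-spread functions (ESF), and its first
derivative is the line-spread function (LSF), which for a symmetric PSF
profiles the PSF directly. The pipeline
(`measure_resolution()`) chains:

1. `extract_profile()` — a single bilinear-interpolated cross-section
   through the bar centers, perpendicular to the bars (orientation
   auto-detected from the ROI when not given);
2. `differentiate()` — central finite differences, **no smoothing**:
   pre-smoothing would bias the LSF width, so noise is left to the fit;
3. `fit_multi_gaussian()` — Levenberg–Marquardt least squares of a
   constant baseline plus one signed Gaussian per transition (six for a
   full element). The Gaussian is a first approximation to the Airy
   profile; its width is the quantity of interest,
   $\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma$.

The mean and standard deviation of the fitted widths give the PSF
estimate; `sampling_assessment()` then counts sensor pixels across the
central peak.

```{r resolution-example}
scene <- scene_config(magnification = 1.2, pixel_pitch = 1.2,
                      psf_fwhm = 3.2, read_noise_sd = 0.017,
                      seed = 7, image_size = c(420, 420))
chart <- render_usaf(scene, groups = 4, elements = 2,
                     orientations = "vertical")
measure_resolution(chart$image, chart$elements[1, ], magnification = 1.2)
```

### Width corrections

The sampled derivative is broadened by two known instrument terms: the
sensor pixel aperture (a boxcar of one pixel pitch, variance $p^2/12$)
and the central-difference kernel (a boxcar of two sample spacings,
variance $h^2/3$). `measure_resolution()` subtracts both from the fitted
$\sigma^2$ by default. The correction is what makes the measurement
honest near the sampling limit: at $M = 0.5$ on a 1.2 µm sensor a
4.3 µm PSF would otherwise read ~30 % too wide. Transitions whose
fitted width falls below the combined kernel width are dropped with a
warning rather than reported as imaginary numbers; disable with
`lsf_correction = FALSE` to see the raw sampled widths.

### Which plane?

Fitted widths are native to the sensor plane (profile positions are
pixel index × pitch). They are reported in **sample-plane micrometers**
(sensor width divided by $M$) by default, because resolution is compared
against sample feature sizes — a 6–7 µm insect-wing hair is or is not
resolvable in sample units. `plane = "sensor"` skips the conversion, and
a report built without a grid image degrades to sensor units with a
warning rather than failing.

### Nyquist rule

The conventional rule of thumb is that roughly 7 samples are needed
across the central peak of an in-focus PSF to describe it fully. The
support of the "central peak" is not standardized; `lenschar` defines it
as `peak_support` × FWHM with `peak_support = 2` (the peak down to ~6 %
of its height), giving

$$\text{points per peak} = \frac{2 \cdot \mathrm{FWHM} \cdot M}{p}.$$

Both the factor and the required count are arguments, not magic
constants.

## Radial distortion

Short-focal-length aspherics show predominantly pincushion distortion in
widefield use. `estimate_distortion()` fits the one-coefficient Brown
model $r' = r(1 + k_1 (r/R_n)^2)$, with $r$ the undistorted radius,
$R_n$ the image half-diagonal (so $k_1$ is comparable across image
sizes) and $k_1 > 0$ meaning pincushion. The distortion center is fixed
at the geometric image center; decentering is not modeled. Grid
intersections are located by iteratively re-centered darkness centroids
followed by a marginal-profile refinement that separates the two
crossing lines (the 2-D centroid alone is biased by up to half the
window-rounding offset through the mass of the crossing line's arms).
The search marches outward from the center, updating a running
$(\text{scale}, k_1)$ fit so the outer intersections are looked for
where distortion has actually pushed them. On synthetic scenes the null
case recovers $|k_1| < 10^{-4}$ and $k_1 = 0.05$ is recovered within a
few percent.

## The synthetic scene generator

Every estimator above is validated against `render_grid()`,
`render_usaf()` and `add_filament_phantom()`, which emulate the study
conditions the pipeline targets: a 500 µm-period grid target (100 µm
variant for distortion work, where more intersections fit the field), a
chrome-on-glass USAF chart, magnifications of roughly 0.5–1.5 onto a
1.2 × 1.2 µm-pixel sensor, PSF FWHM of ~2–10 µm, pincushion distortion,
vignetting, and sensor noise. Design choices:

* **Analytic rendering.** The ideal pattern is rasterized by exact
  pixel-aperture integration (each pixel value is the covered area
  fraction of its footprint), so edge positions carry sub-pixel
  information without supersampling artifacts.
* **Optics order** in `apply_optics()`: magnification resampling →
  radial distortion (inverse-mapped, bilinear) → PSF convolution at
  sensor resolution (Gaussian kernel truncated at ±4σ, or an Airy
  kernel with first zero at $0.61\lambda/\mathrm{NA}$ truncated at its
  third zero; kernels normalized to sum 1; edge-replicated borders) →
  multiplicative vignette $1 - v(r/R_n)^2$ → Poisson shot noise then
  Gaussian read noise.
* **Determinism.** The scene seed drives both noise sources through a
  local RNG state; identical configurations give bit-identical images
  and the caller's RNG stream is untouched.
* The Gaussian PSF is the default (matching the Gaussian fit model);
  the Airy option exists for realism checks.
* Noise levels in validation use edge SNR 50, i.e. read-noise SD =
  (bright − dark)/50 — moderate, realistic for a well-lit target
  exposure.

What the generator does **not** emulate — and therefore what passing
synthetic tests cannot show about real images: chromatic aberration,
field curvature, coma and astigmatism; focus error across a tilted or
curved field; camera ISP behavior (demosaicing, sharpening, denoising,
autofocus hunting); illumination structure beyond a smooth radial
falloff; dust and target defects. Real-image use should expect edge
placement and white-balance effects the synthetic suite never sees.

## Validation problem sizes

The bundled test-suite and validation runs use grid images of about
2.2 periods across (≈460–1400 px depending on $M$), single-element USAF
scenes of ≈270–390 px, 10 noise seeds per condition for stochastic
checks, and the five study configurations
$(M, \mathrm{FWHM}) \in \{(1.5, 2.3), (0.9, 2.9), (1.2, 3.2), (0.5, 4.3),
(0.7, 9.2)\}$. These sizes keep a full validation run in the low minutes
on one core while leaving every estimate's tolerance comfortably
resolvable.

## Numerical choices and degenerate inputs

* Fit convergence: relative tolerance $10^{-8}$ on the residual norm,
  iteration cap 500; non-convergence is a typed error
  (`lenschar_fit_error`) carrying diagnostics, never a silent result.
* Peak detection threshold: 5 × a robust noise estimate (1.4826 × MAD
  of the derivative tails, the outer 10 % of samples at each end), with
  a small relative floor so noiseless profiles behave; candidate extrema
  must alternate in sign (within a same-sign run the strongest
  survives).
* Initialization: centers at sub-pixel-refined extrema; widths the
  smaller of half the neighbor distance and the peak's own half-maximum
  support (the neighbor distance alone, for well-separated bar edges,
  starts an order of magnitude too wide and stalls the optimizer);
  amplitudes from the extremum values.
* Ties in `smallest_resolvable_element()` break toward the coarser
  element; its scan requires three distinct below-midline bar minima
  before computing Michelson modulation.
* Degenerate scenes (field smaller than one grid period, uniform
  images, sub-pixel chart elements, out-of-bounds profiles, non-invertible
  distortion with $k_1 \le -1/3$) raise typed conditions
  (`lenschar_degenerate_scene`, `lenschar_insufficient_structure`,
  `lenschar_geometry_error`, `lenschar_domain_error`) so pipelines can
  degrade deliberately — `characterize_lens()` records stage failures in
  the report notes and marks the report partial.
* Rayleigh predictions in reports default to λ = 550 nm, the center of
  the visible band, when no wavelength is configured.

## Known limitations

* The Gaussian LSF model underfits heavily aberrated or defocused PSFs
  whose true profile is multi-lobed; the per-element SD of the six
  widths is the built-in warning sign.
* The distortion model is single-coefficient and centered; strong
  decentering or tangential distortion will surface as residual RMS.
* Cross-section placement on real chart photographs (the exact line the
  red selection would follow) is the dominant unquantified uncertainty
  when reproducing published measurements; synthetic scenes sidestep it
  because the element map is exact.
* The comparison table deliberately computes no composite score: lens
  choice trades resolution against field of view, working distance and
  cost, and that judgment is left to the user.
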