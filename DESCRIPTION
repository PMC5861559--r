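Package: lenschar
Title: Optical Characterization of Low-Cost Microscope Lenses from
    Calibration-Target Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to measure the optical performance of simple microscope
    objectives (for example single aspheric lenses in smartphone microscopes)
    from images of standard calibration targets.  Magnification and radial
    distortion are estimated from grid distortion targets; the point spread
    function is measured by differentiating edge cross-sections through USAF
    1951 chart elements and fitting multi-peak Gaussians to the resulting line
    spread functions; Rayleigh-criterion predictions and Nyquist sampling
    adequacy are computed from lens specifications.  A synthetic-target
    renderer with a full forward imaging model (magnification, pincushion
    distortion, Gaussian or Airy blur, vignetting, sensor noise) provides
    ground-truth scenes for validation, and per-lens results are aggregated
    into comparison tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
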