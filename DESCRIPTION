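Package: mothvis
Title: Optics and Opsin Spectral Analysis for Nocturnal Moth Visual Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the visual system of nocturnal moths from
    simple physical measurements. Computes anatomical resolution, F-number and
    optical sensitivity of superposition compound eyes; analyses hanging-drop
    measurements of ocellar lenses (back focal distance, focal length from
    grating magnification, Michelson contrast and optical cutoff frequency);
    and models visual-pigment absorbance with the Govardovskii A1 template,
    estimating lambda-max by nonlinear least squares with bootstrap confidence
    intervals, difference spectra for acid-denaturation assays and retinal-oxime
    peak checks. Includes deterministic synthetic-data generators (noisy pigment
    spectra, blurred gratings, focus series, chromatic lens datasets) so every
    analysis stage can be validated against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
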