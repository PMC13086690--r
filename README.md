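# mothvis

Quantitative tools for the visual system of nocturnal moths: superposition
compound-eye optics, ocellar lens measurements, and visual-pigment
spectral analysis.

Nocturnal insects that navigate by starlight operate at the edge of what
optics allows. Three numbers summarize how well a compound eye gathers
light: the interommatidial angle Δφ = D/R (anatomical resolution, facet
diameter over eye radius), the F-number F = f/A (image brightness, focal
length over superposition-pupil diameter), and the optical sensitivity

    S = (π/4)² A² (d/f)² · kl / (2.3 + kl)   [µm² sr]

for rhabdom diameter d, absorbing length l and absorption coefficient k.
`mothvis` computes these with explicit unit and provenance handling
(including the doubling of rhabdom length by a reflective tapetum), and
compares eyes via brightness and sensitivity ratios.

For the simple lens eyes (ocelli), the package analyses hanging-drop
measurements: back focal distance from a z-stack focus series, focal
length from grating magnification (f = s₀ · λᵢ/λ₀), Michelson contrast
of imaged gratings, and the optical cutoff frequency from the x-intercept
of a contrast-versus-frequency regression — plus descriptive group
summaries that expose chromatic aberration and astigmatism.

For visual pigments, it implements the Govardovskii A1 absorbance
template (alpha + beta bands), fits λmax by deterministic nonlinear least
squares (closed-form amplitude, 1-nm grid scan, 0.01-nm refinement), and
attaches case-resampling bootstrap 95% confidence intervals. Difference
spectra (dark − acid-denatured) isolate pigments from free-retinal
contamination; oxime-peak checks confirm functional pigments; and the 5%
long-limb threshold gives a pigment's red limit of useful sensitivity.

Deterministic synthetic-data generators (noisy template spectra, blurred
gratings, focus series, chromatic lens datasets) carry their ground truth
in metadata so every estimator is testable without instrument data.

## Worked example

```r
library(mothvis)

geom <- eye_geometry(
  facet_diameter_um = 22, eye_radius_um = 969, focal_length_um = 485,
  aperture_um = 857, rhabdom_diameter_um = 10,
  rhabdom_length_physical_um = 47, has_tapetum = TRUE)
optical_metrics(geom)
#> Compound-eye optical metrics
#>   interommatidial angle : 1.3 deg
#>   F-number              : 0.566
#>   effective rhabdom     : 94 um
#>   optical sensitivity S : 41.4 um^2 sr

brightness_ratio(f_number(485, 857), f_number(16700, 8000))
#> [1] 13.57341   # the moth's image is ~13.6x brighter than ours

threshold_wavelength(547)   # red limit of a 547-nm pigment
#> [1] 646.8666

s   <- make_spectrum(547, noise_sd = 0.01, seed = 42)
fit <- fit_lambda_max(s, n_boot = 1000, seed = 42)
fit
#> <template_fit> lambda_max = 547.0 nm (amplitude 0.98, rss 0.0355)
#>   95% CI [546.9, 547.2] nm (1000 bootstrap replicates, seed 42)
```

A Δφ of 1.3° and S ≈ 41 µm² sr are typical of highly light-adapted
nocturnal superposition eyes; the fitted λmax recovers the generator's
ground truth with a sub-nanometre interval at this noise level.

See `vignettes/mothvis-methods.Rmd` for the models, parameter choices and
limitations.

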