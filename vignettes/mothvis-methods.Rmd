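---
title: "Methods: eye optics, ocellar lens measurements and pigment template fitting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eye optics, ocellar lens measurements and pigment template fitting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mothvis)
```

`mothvis` quantifies three aspects of a nocturnal moth's visual system —
the light-gathering optics of its superposition compound eyes, the image
formation of its ocellar lenses, and the spectral tuning of its visual
pigments — from simple physical measurements. This vignette explains the
models behind each module, the parameters that matter, the numerical
choices made, and what the synthetic-data generators do and do not
emulate.

## Superposition eye optics

Three classical quantities summarize a compound eye's optics.

**Anatomical resolution.** The interommatidial angle is the facet spacing
divided by the eye's radius of curvature, $\Delta\phi = D/R$ in radians.
Internally all angles are radians; reporting is in degrees, the unit of
the comparative literature. For a 22 µm facet on a 969 µm eye,
$\Delta\phi = 1.30°$.

**Image brightness.** The F-number $F = f/A$ uses the *superposition*
aperture $A$ — the diameter of the pupil formed by the hundreds of facets
that jointly illuminate each rhabdom, observable as the eye glow — not a
single facet. Retinal image brightness for an extended scene scales as
$1/F^2$, so `brightness_ratio()` compares two eyes as $(F_b/F_a)^2$.

**Optical sensitivity.**
$$S = \left(\tfrac{\pi}{4}\right)^2 A^2 \left(\tfrac{d}{f}\right)^2
      \frac{kl}{2.3 + kl} \qquad (\mu m^2\,sr)$$
with rhabdom diameter $d$, focal length $f$, absorbing length $l$ and
absorption coefficient $k$. The default $k = 0.0067\ \mu m^{-1}$ is the
standard value measured in crustacean rhabdoms; it is an explicit field
in every saved report so its provenance stays visible. When a reflective
tracheolar tapetum backs the retina, light traverses the rhabdom twice;
`effective_rhabdom_length()` makes that doubling an explicit operation so
physical anatomy (e.g. 47 µm) and effective absorbing length (94 µm) are
never conflated. As $l \to \infty$ the absorption term saturates at 1 and
$S$ approaches its supremum $(\pi/4)^2 A^2 (d/f)^2$; the property tests
verify the exact $A^2$ and $(d/f)^2$ scalings and this saturation.

`eye_geometry()` warns — rather than errors — when the aperture is
smaller than a facet, because for apposition eyes (honeybee) the two
coincide and the same container is convenient for cross-species
comparisons. Report output rounds to 3 significant figures, matching the
precision such measurements support.

## Ocellar lens optics from hanging-drop measurements

A dissected ocellar lens suspended on a water droplet projects a distant
grating; a microscope z-stack through the aqueous image space locates the
plane of best focus.

**Back focal distance.** `back_focal_distance()` takes the frame count
between the sharpest frame (argmax of any unimodal focus score,
optionally smoothed by a centred moving average) and the lens back
surface, times the z-step, times the refractive index of the medium
(water, 1.33). Any sharpness score is accepted — per-frame intensity
variance is typical — which keeps the operation testable without image
processing. A flat score series is an estimation error; an argmax at the
stack boundary warns, since the true focus may lie outside the stack.

**Focal length.** With the grating at effective infinity ($s_0 \ge 100$
mm; closer distances warn), $f = s_0 \times$ (image period / object
period). The period ratio is the linear magnification; the implementation
follows this magnification reading of the lens equation and documents it,
since the two periods are easily transposed in prose.

**Contrast and cutoff.** Michelson contrast
$M = (I_{max}-I_{min})/(I_{max}+I_{min})$ is extracted from a greyscale
line profile perpendicular to the stripes after optional smoothing
(default: none) and trimming 10% of samples at each edge, where the
imaged patch's border contaminates the profile. At least two full periods
must survive trimming. Contrast falls with spatial frequency until the
stripes are no longer discernible; `cutoff_frequency()` fits an
*unweighted* ordinary least-squares line to contrast versus frequency and
reports its x-intercept $f_c = -b_0/b_1$. Points at or below a contrast
floor (default 0.02) sit in the flat noise tail, would otherwise lever
the regression, and are excluded from the fit while staying in the
record; a floor of 0 disables the exclusion. A non-negative slope means
no cutoff exists and is an error, not a number.

**Chromatic aberration and astigmatism** are summarized descriptively:
per-color and per-orientation group means, sample standard deviations and
counts (`summarize_lens_measurements()`). Groups with one value report
sd = 0 with n = 1. Mixed-model inference over ocellus random effects is
deliberately out of scope; the generator nevertheless includes a
per-ocellus random intercept so grouped summaries face realistic
clustering.

## Visual-pigment template fitting

**The template.** `govardovskii_a1()` implements the standard A1
(11-*cis*-retinal) visual-pigment absorbance template: an alpha band
$$S_\alpha(x) = \left[e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D\right]^{-1},
\quad x = \lambda_{max}/\lambda,$$
with $A=69.7$, $B=28$, $C=-14.9$, $D=0.674$, $b=0.922$, $c=1.104$ and
$a = 0.8795 + 0.0459\,e^{-(\lambda_{max}-300)^2/11940}$, plus a Gaussian
beta band of amplitude 0.26 centred at $189 + 0.315\,\lambda_{max}$ with
width $-40.5 + 0.195\,\lambda_{max}$. These constants are fixed
literature values, not tunable parameters. The beta band is included by
default; `include_beta = FALSE` exposes the alpha-only behaviour, since
published fits do not always state which was used. An A2 template is not
implemented: the pigments modelled here are reconstituted with
11-*cis*-retinal.

**Fitting.** `fit_lambda_max()` minimizes
$\sum_i (A_i - \alpha T(\lambda_i;\lambda_{max}))^2$ over
$(\lambda_{max}, \alpha)$. For any candidate peak the optimal amplitude
is a linear least-squares projection with a closed form, so the problem
is a 1-D search: a coarse 1-nm grid scan over the search bounds followed
by local refinement (`stats::optimize`) to 0.01 nm. This deterministic
nested scheme was chosen over generic black-box minimizers for exact
reproducibility; a test asserts agreement with an independent `nls` fit
and with an exhaustive 0.01-nm grid search to within 0.05 nm. The
spectrum is normalized to unit maximum inside the fit window (this does
not move the optimum). Candidates whose optimal amplitude is non-positive
are invalid; a flat spectrum is a fit failure; an optimum at a search
bound warns. Reported peaks carry 0.1 nm precision. An optional additive
baseline can be co-estimated in closed form but is off by default — a
free baseline can silently absorb a contaminant shoulder.

**Fit window and free retinal.** UV pigments absorb where unbound
(non-covalently attached) retinal also absorbs. Two documented remedies:
restrict `fit_window_nm`, or fit the acid-denaturation *difference
spectrum*, in which the contaminant — identical in the dark and
acid-denatured measurements — cancels, leaving a positive lobe at the
pigment peak and a negative lobe at the protonated photoproduct
(~436 nm). `difference_spectrum()` defaults to dark-minus-acid. When
fitting the difference of a UV pigment, the window should stop below the
photoproduct's short-wavelength limb (about 375 nm for a 362-nm pigment
with a 436-nm photoproduct); the synthetic-data test demonstrates that a
direct fit of a contaminated spectrum is pulled several nm toward the
380-nm contaminant while the windowed difference workflow recovers the
true peak to within 2 nm.

**Bootstrap confidence intervals.** `bootstrap_ci()` case-resamples the
(wavelength, absorbance) pairs with replacement, refits each replicate,
and takes the 2.5th/97.5th percentiles of the recovered peaks (default
1000 replicates). Case resampling of points was chosen because the
resampling unit is rarely stated in published fits and it requires no
residual-exchangeability assumption. The seed is mandatory and recorded;
identical seeds give identical intervals. Replicates that fail (no
positive-amplitude candidate, or peak pinned at a bound) are dropped;
more than 10% failures flags the interval unreliable. For speed the
candidate-template matrix on the spectrum's grid is computed once and
each replicate is scored against row-subsets of it in closed form —
algebraically identical to refitting. The acceptance suite verifies
~95% empirical coverage over 200 simulated spectra (noise sd 0.02) with
400 replicates per interval, a problem size chosen to keep the full
suite under a few minutes; percentile intervals are insensitive to the
replicate count beyond this.

**Derived spectral limits.** `threshold_wavelength()` solves
$T(\lambda) = \ell$ on one limb by bisection to 0.01 nm. The 5% level on
the long limb gives the conventional red limit of useful sensitivity: for
a 547-nm pigment this is ≈647 nm, versus ≈621 nm for a 525-nm pigment —
the basis for comparing long-wavelength reach across species. On the
short limb the beta band can keep the template above low levels
throughout, in which case there is no crossing and the function says so.

## Synthetic data: what it emulates, and what it does not

Every generator takes a mandatory seed, stores its full ground truth in
the output's `ground_truth` attribute, and is bit-reproducible. Recovery
tests read truth only from that metadata. Noise is i.i.d. Gaussian
throughout — measurement noise models are rarely published, and Gaussian
noise is the neutral default.

- `make_spectrum()`: unit-amplitude template + flat baseline + optional
  free-retinal band (Gaussian at 380 nm, sd 30 nm, centred within the
  350–450 nm range where unbound retinal absorbs) + noise.
- `make_grating_profile()`: mean-128, amplitude-127 sine or square wave
  sampled in degrees, circularly convolved (exact for whole periods) with
  a Gaussian blur; for sines the closed-form modulation transfer
  $e^{-2\pi^2\sigma^2 f^2}$ is recorded as truth. Defaults: 64
  samples/period, 4 periods.
- `make_zstack()`: unimodal Gaussian focus-score profile with its peak at
  the frame implied by the requested back focal distance (default width
  6 µm, a sharp but realistic depth of focus for a ~200-µm focal-length
  lens).
- `make_lens_dataset()`: per-color back focal distances (defaults red 40,
  green 35, blue 30 µm, total sd 10 µm — matching the observed chromatic
  spread) and focal lengths (190 ± 24 µm), with a per-ocellus random
  intercept (half the total sd) plus residual, over 3 colors × 4
  orientations.

What passing these tests shows is that the *estimators* are correct and
unbiased under their stated models. What they cannot show: real
absorbance spectra have wavelength-correlated noise and instrument
baselines; real focus scores are asymmetric around the focal plane; real
gratings suffer non-Gaussian aberrations and vignetting; real lens
datasets have unbalanced designs. Conclusions about an instrument's data
still require inspecting fit residuals.

## Numerical choices and limitations

- Grid scan at 1 nm before refinement: the RSS landscape of the template
  in $\lambda_{max}$ is smooth with basins far wider than 1 nm, so the
  scan cannot miss the global optimum; refinement tolerance 0.005 nm
  comfortably beats the 0.1 nm reporting precision.
- Bisection brackets: long limb (peak, 800 nm], short limb [300 nm,
  peak); a missing sign change raises a no-crossing error rather than
  extrapolating.
- Moving averages shrink their window at sequence edges rather than
  padding.
- Ties in an argmax resolve to the first (shallowest) frame or
  wavelength; with continuous scores ties are measure-zero.
- `run_pipeline()` isolates stage failures (a failing stage is recorded;
  independent stages still run) and is deterministic given config and
  seed; only the report timestamp differs between reruns.
- Problem sizes in the shipped test suite (50 recovery seeds per pigment,
  200 coverage simulations at 400 bootstrap replicates, 100 z-stack
  seeds) were chosen as the smallest sizes at which the binomial/Monte
  Carlo error of each check is well below its tolerance.
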