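---
title: "Methods: macular thickness mapping, foveal pit morphometry, and normative effects modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: macular thickness mapping, foveal pit morphometry, and normative effects modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the measurement pipeline, the statistical model, the synthetic cohort
that validates both, and the numerical and design choices that were
genuinely open.

## The measurement pipeline

A segmented macular OCT acquisition gives, for each eye, scattered
samples `(x, y, thickness)` for six layers over a 6 x 6 mm raster: total
retinal thickness (TRT) and the five non-overlapping layers RNFL, GCIPL,
INL, ONPL and ELM-BM whose sum is the TRT (an invariant the package
enforces everywhere, to 0.01 µm on file ingest).

**Fovea alignment.** All analysis is fovea-centered. The center is the
arg-min of a smoothed TRT map: samples are interpolated to a coarse
0.05 mm grid, convolved with an isotropic truncated Gaussian
(σ = 0.15 mm, cut at 3σ, kernel renormalized at edges so constants are
preserved), and minimized over the central 2 x 2 mm window. Ties are
broken toward the raster center, then lexicographically — so a
degenerate constant field yields the window center rather than an
error. The kernel width is a package choice (the smoothing scale is not
fully specified by the upstream description); it is validated by
translation-equivariance and recovery tests rather than against a
reference implementation. Left (OS) eyes are mirrored in x after
centering, giving a single right-eye frame with +x nasal and +y
superior.

**Interpolation.** Thickness fields are evaluated on a 300 x 300 regular
grid. The upstream description of that grid ("300 x 300, 0.1 mm
spacing") is internally inconsistent — 300 nodes at 0.1 mm would span
30 mm, five times the scanned field. We keep the stated field (6 x 6 mm)
and the stated resolution (300 nodes), i.e. 0.02 mm spacing; the choice
is recorded in the run manifest. Because every supported acquisition is
a regular raster (25 x 512 or 97 x 1024, and fixation offsets or
mirroring only translate/reflect the grid), interpolation is separable
piecewise-linear (bilinear) on the raster: exact at sample positions,
exact for affine fields, no overshoot, and no extrapolation — grid nodes
beyond the sampled extent are missing and excluded from averages.

**Sectorization.** Three schemes, all fovea-centered and all defined as
unweighted means over grid nodes: the whole macula (disc of radius
3 mm); the ETDRS grid (central disc of 1 mm diameter; inner ring 1–3 mm
and outer ring 3–6 mm diameters split by the ±45° diagonals into
nasal/superior/temporal/inferior quadrants, with the outer ring clipped
to the analyzed 3 mm circle); and a 20 x 20 grid of 0.3 mm square
cells. A cell is retained when its center lies inside the 3 mm circle —
316 of the 400 cells, a count the test suite re-derives by brute force.
For RNFL, GCIPL and INL the central 1.2 x 1.2 mm (16 cells) is also
excluded, because inner-layer thickness is near zero there and sector
means would be dominated by segmentation error; 300 cells remain.
Boundary conventions are deterministic: nodes exactly on a ring circle
belong to the inner ring, angular wedges are half-open, and nodes on a
cell edge belong to the larger row/column index. The node-weighted mean
of the retained cells reproduces the whole-macula mean on the same node
mask exactly — a conservation property the acceptance suite checks to
machine precision.

**Foveal pit morphometry.** TRT is resampled along 24 directions (15°
steps, 0° = nasal, counterclockwise) at radii 0, 0.1, …, 2 mm, with the
center value shared. Per direction:

* CFT — the raw (unsmoothed) TRT at r = 0. Whether the original value
  was read from the raw or smoothed profile is not documented upstream;
  we use raw and flag the choice.
* LOESS smoothing, span 50%: at each radius, a weighted quadratic fit
  over the nearest ⌈span·n⌉ = 11 neighbours with tricube weights on
  distance scaled by the furthest included neighbour. The local degree
  is quadratic because the rim is a curvature feature. The smoother is
  defined exactly (and tested against a brute-force per-point weighted
  least squares oracle at 1e-9, and against `stats::loess(surface =
  "direct")`), because the rim position feeds three downstream
  parameters.
* Rim — arg-max of the smoothed profile over r > 0 (ties to the
  smallest radius: the nearest anatomical rim); rim height is the
  smoothed value there, rim radius the corresponding radius. An arg-max
  at r = 2 mm is flagged `rim_at_boundary`.
* Mean slope — the mean of `atan(ΔT/Δr)` over the forward-difference
  steps from the center to the rim, computed on the *unsmoothed*
  profile, in degrees (thickness converted to mm). "Mean first
  derivative in degrees" is ambiguous between the mean of per-step
  angles and the angle of the mean slope; we take the former, since
  degree units imply per-point angles, and note that with the default
  geometry it yields ≈ 6.2°, consistent with the derived young-group
  value (0.39 µm / 6.23% ≈ 6.3°).

Whole-macula pit parameters are unweighted means over the 24 directions
(CFT passes through; it does not vary radially).

## The statistical model

Each parameter is modelled at the eye level with a subject random
intercept to absorb inter-eye correlation:

y = β₀ + β_sex·isMale + β_age·age (+ β_age2·age²) + β_sf·scanFocus + γ_subject + ε

* **ML, not REML.** AIC comparison and likelihood-ratio tests across
  fixed-effect structures require maximum likelihood; the upstream
  description does not state the likelihood type, so ML is used for
  everything.
* **Age centering.** Age is centered at 40 years before fitting to
  de-correlate the linear and quadratic terms; reported quantities are
  mapped back. Age 40 is also the young-group reference, which makes
  the percent normalization exact by construction in the generator.
* **Model selection.** Linear vs quadratic age by lower AIC; exact ties
  prefer the linear model.
* **Combined age effect.** The mean yearly change between 40 and 80 —
  `(ŷ(80) − ŷ(40))/40 = b1 + 40·b2` in centered coefficients — reported
  per decade, with a Wald normal CI on the linear combination. This
  makes linear and quadratic fits comparable on one scale.
* **Combined age p-value.** For quadratic selections, a 2-df
  likelihood-ratio χ² between the no-age and quadratic ML fits. The
  upstream text calls this an F-test; exact F denominators are
  ill-defined for mixed models, and at n ≈ 855 the difference is
  negligible. For linear selections, the Wald p of the age slope.
* **Percent transforms.** Age effects divided by the mean parameter
  value among eyes of subjects aged ≤ 40 (the Methods' "≤ 40" wins over
  figure captions saying "< 40"); sex effects by the young *female*
  mean. CI bounds are rescaled by the same scalar (whether the original
  re-derived them on the percent scale is unknowable; rescaling is the
  conservative choice).
* **Multiplicity.** Holm for the whole-macula families (12 thickness
  tests: 6 layers x {age, sex}; 8 foveal tests: 4 parameters x {age,
  sex}); Benjamini-Hochberg for the ETDRS/20 x 20 sector maps, where
  tests are many and spatially dependent.
* **Marginal R².** `var(Xβ̂) / (var(Xβ̂) + σ²_γ + σ²_ε)`, the share of
  variance explained by fixed effects alone.
* Wald CIs with normal quantiles throughout (the CI method is not
  documented upstream). Degenerate fits (boundary variance estimates)
  return NA uncertainty rather than failing.

## The synthetic cohort generator

No raw data accompany the normative study this package emulates, so the
generator *is* the study population for validation purposes. Its
defaults are fixed study conditions, not tuning knobs.

**Demographics.** 444 subjects; each contributes both eyes with
probability 411/444 (855 expected eyes). Ages are uniform within four
buckets `[21,40) / [40,60) / [60,80) / [80,88]` weighted by the printed
bucket counts 51/212/161/8 — which sum to 432, not 444, an upstream
inconsistency we resolve by normalizing the weights. Sex is
Bernoulli(281/444 female); scan focus ~ Normal(0, 1.5 D). The
bucket-uniform mixture has sd(age) ≈ 14.6 y, wider than the study's
12.7 y — a known, documented difference that propagates into the
marginal R² (below).

**Effect sizes.** Per-layer reference means are derived as the ratio of
the printed absolute to percent coefficients (e.g. TRT 3.25/1.05% →
309.5 µm; the study never prints group means), with the five layer
means renormalized to sum exactly to the TRT mean. Age and sex
coefficients are the printed per-layer values; the layer sex effects
sum exactly to the printed TRT value (4.14 µm), while the layer age
effects sum to −3.11 µm/decade against a printed TRT value of −3.25 —
an upstream rounding inconsistency; since TRT is structurally the layer
sum, the injected TRT age effect is −3.11 (−1.005%/decade, inside the
printed CI). Layers flagged quadratic split their combined effect c as
b1 = 0.9c, b2 = 0.0025c (the quadratic term carries 10% of the 40–80
change); at that curvature AIC usually still selects the linear form,
which is immaterial because the combined effect is the reported
quantity either way. Scan-focus effects total 1 µm/D, allocated across
layers proportionally to their means (invented: the effect only needs
to be recoverable).

**Noise.** The TRT subject intercept (14 µm) and eye residual (6 µm)
are fixed defaults; layer SDs scale with layer means, normalized so the
five independent layer noises sum in variance exactly to the TRT
values. Under this generator's demographics the emergent TRT marginal
R² is ≈ 10–13% rather than the study's 8.2% (the wider age distribution
raises the fixed-effect variance); the test suite therefore checks the
analytically derived expectation for *this* generator, not the printed
value. Pit-parameter noise (not specified anywhere) is calibrated
analytically from the generator's exact demographic moments so each
pit parameter's marginal R² matches its printed value, with the same
196:36 intercept:residual variance split as TRT.

**Surfaces.** In *grid mode* each layer is a fixed radial template
scaled so the eye's true disc mean equals its mean model value: RNFL
grows as (r/3)³ (near zero centrally), GCIPL and INL rise steeply
around 0.5 mm to annular maxima near 1–1.2 mm (inner-layer thickness
stays below 1 µm inside r = 0.3 mm), ONPL has a broad central mound
peaking slightly off-center so the TRT minimum is strictly at the
fovea, and ELM-BM is near flat. The templates are invented anatomy:
smooth, radially symmetric stand-ins with realistic central and rim
values, normalized to disc mean 1 by radial quadrature. In *pit mode*
the TRT surface is the closed form

T(r, θ) = CFT + (H(θ) − CFT) · g(r/R(θ)),  g(u) = uᵃ·exp(a(1−u))

with shape a = 2 (chosen once so the emergent mean slope ≈ 6.2°
matches the derived young-group value), rim radius modulated by
1 + 0.1·cos 2θ (broader horizontally, as real foveae are) and rim
height by 1 + 0.01·cos 2θ. CFT, rim height and rim radius each follow
their own effect models; the mean slope is *emergent*, and its
recovered sex difference (≈ +0.25°) is smaller than the printed +0.39°
because only radius and height differences — not pit shape — carry sex
information in the generator. Layers in pit mode are a documented
synthetic convention (flat ELM-BM floor, remainder in ONPL, inner
layers zero) that preserves the additivity invariant.

**Acquisition.** Samples are evaluated on the protocol raster (25 x 512
or 97 x 1024 over ±3 mm) after a per-eye fixation offset drawn
uniformly from a 0.3 mm disc (exercising fovea localization without
leaving the raster); OS eyes are mirrored. The paired sensitivity
cohort evaluates the *same* true surface, with the same offset, on both
rasters — no per-sample measurement noise is modelled (speckle and
segmentation error are out of scope), so protocol differences are pure
discretization effects: the 0.25 mm B-scan spacing interpolates across
the pit minimum (convexity biases CFT upward) and flattens the profile
(biasing the mean slope down), while disc-averaged layer means are
essentially protocol-invariant (< 1%). The real-world bias magnitudes
depend on true foveal sharpness, which the generator does not claim to
know; signs and the < 1% thickness robustness are the validated
properties.

## Numerical choices and degenerate inputs

* Determinism: every random draw descends from one integer seed;
  regenerating a cohort with the same config and seed is byte-identical
  on disk.
* Serialization: 6 significant digits; additivity re-imposed after
  rounding so readers always see consistent files.
* Whole-macula means with an off-center fovea use only nodes inside the
  sampled extent (the clipped crescent is at most ~2% of the disc).
* LOESS requires ≥ 5 points and strictly increasing radii; duplicated
  radii are an error, as is a radial grid node outside the sampled
  area (reported with the offending nodes).
* Monotone-decreasing profiles put the rim at the first radial step
  (tie rule); monotone-increasing profiles carry the boundary flag.
* lme4 boundary fits (singular random-effect variance) are accepted and
  their Wald uncertainty reported as NA if the covariance computation
  fails.

## Problem sizes used by the test suite

The full validation — 444-subject cohorts in both modes — runs in a few
minutes per seed. The packaged test suite sizes simulations to stay
fast while keeping the statistics meaningful: the parameter-recovery
suite runs 4 replicate cohorts at full subject count (with the
thickness maps on a 120-node grid, which changes disc means by well
under 0.1 µm) and pools coverage across its eight tracked quantities;
the type-I calibration uses 1000 refitted replicates of a fixed
120-subject design; the sensitivity checks use the 12-subject paired
design of the emulated study. `recovery_suite(n_seeds = 20)` reproduces
the full-scale recovery experiment.

## Known limitations

* The generator's radial templates and pit shape are parametric
  stand-ins, not fitted anatomy; passing recovery tests demonstrates
  that the *pipeline* is unbiased and calibrated under known truth, not
  that real retinas look like the templates.
* Ocular magnification / lateral scaling, axial-length optics, raw
  B-scan simulation, speckle and segmentation error are out of scope.
* Sex x age interactions are deliberately not modelled.
* The mean-slope sex difference is attenuated relative to the printed
  value for the structural reason discussed above.
* Scattered (non-raster) sample layouts are rejected rather than
  triangulated; all supported acquisitions are rasters.
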