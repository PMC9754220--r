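# octmorph

Spatial morphometry of the human macula from segmented optical coherence
tomography (OCT) scans, with mixed-effects normative modelling of age and
sex effects — plus a fully specified synthetic cohort generator so the
entire pipeline is testable end to end without access to patient data.

`octmorph` is aimed at researchers building normative references for
macular layer thickness and foveal pit shape: it reproduces, as reusable
R functions, the analysis chain

1. **Fovea alignment** — the foveal center is located as the arg-min of a
   Gaussian-smoothed total retinal thickness (TRT) map; left eyes are
   mirrored so all data live in a right-eye frame (+x nasal, +y superior).
2. **Thickness mapping** — scattered A-scan samples of six layers (TRT,
   RNFL, GCIPL, INL, ONPL, ELM-BM) are interpolated to a 300 x 300 regular
   grid over the central 6 x 6 mm.
3. **Sectorization** — maps are averaged over the whole macula (3 mm
   radius disc), the 9-sector ETDRS grid, and a 20 x 20 grid of 0.3 mm
   cells (316 cells inside the 3 mm circle; 300 for the inner layers,
   whose central 1.2 x 1.2 mm is excluded).
4. **Foveal pit morphometry** — TRT is resampled along 24 radial
   directions (0-2 mm, 0.1 mm steps); per direction, LOESS smoothing
   (span 50%, local quadratic) locates the rim, giving the central foveal
   thickness (CFT), rim height, rim radius, and the mean slope (mean
   forward-difference `atan(dT/dr)` on the raw profile, in degrees).
5. **Effects modelling** — for every parameter `y`, maximum-likelihood
   mixed models with a subject random intercept `γ`:

   `y = β0 + β_sex isMale + β_age age (+ β_age2 age²) + β_sf scanFocus + γ + ε`

   The linear and quadratic age models are compared by AIC; a combined
   age effect (mean yearly change between 40 and 80, reported per decade)
   unifies both forms; a 2-df likelihood-ratio test gives the combined
   age p-value; effects are also reported as percent of the young group
   (age ≤ 40) mean; Holm (whole-macula families) and Benjamini-Hochberg
   (sector maps) control multiplicity; marginal R² reports the variance
   explained by the fixed effects.
6. **Protocol sensitivity** — paired acquisition of the same eyes under
   the standard (25 B-scans x 512 A-scans) and high-resolution (97 x
   1024) rasters, with the undersampling bias estimated per parameter by
   `y = β0 + β_bias isStandard + γ`.

The synthetic cohort generator (`oct_config()`, `simulate_cohort()`,
`generate_cohort()`) emulates the demographic structure of a 444-subject
/ 855-eye normative study (ages 21-88 in four weighted buckets, 63%
female) and injects known age/sex/scan-focus effects for every layer and
pit parameter, so each printed normative estimate becomes a
parameter-recovery target for the pipeline.

## Worked example

```r
library(octmorph)

# a small synthetic cohort: 40 subjects, both modes share demographics
cfg <- oct_config(n_subjects = 40)
cohort <- simulate_cohort(cfg, seed = 1)
tab <- analyze_cohort(cohort)           # generate + align + map + average
eff <- estimate_effects(tab, c("TRT", "GCIPL"))
eff[, c("parameter", "model_form", "beta_age_pct_per10y",
        "beta_sex_abs", "r2_marginal_pct")]
```

```
  parameter model_form beta_age_pct_per10y beta_sex_abs r2_marginal_pct
1       TRT     linear           -1.201443     1.279038        18.88575
2     GCIPL     linear           -2.442718    -1.042788        33.07517
```

At this small size the estimates are noisy but already close to the
injected ground truth for the age effects (TRT −1.005%/10 y, GCIPL
−2.41%/10 y); sex differences (truth +4.14 and +0.57 μm) need the full
cohort to emerge from the noise, and the marginal R² is inflated at
small n by estimation variance. `run_pipeline(cfg, out_dir, seed)` executes the whole
chain — both cohort modes, effects tables with the 12- and 8-test Holm
families, the 12-subject paired sensitivity analysis — and writes CSV
tables plus a run manifest.

For a single eye:

```r
cfg_pit <- oct_config(n_subjects = 40, mode = "pit")
scan  <- sample_eye(sample_demographics(cfg_pit, 1)[1, ], "OD", cfg_pit,
                    seed = 7)
center <- find_fovea(scan)              # (x, y) in mm, device frame
norm  <- normalize_eye(scan, center)    # fovea-centered, right-eye frame
pit   <- fovea_pit_metrics(norm)
pit$aggregate
```

```
$cft_um          216.9531
$rim_height_um   311.9449
$rim_radius_mm   0.9958333
$mean_slope_deg  5.454641
$rim_at_boundary FALSE
```

(This particular simulated eye is a 56-year-old female with a shallower,
narrower pit than the population reference.)

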