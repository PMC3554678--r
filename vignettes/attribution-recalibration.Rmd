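---
title: "Error attribution and sensorimotor recalibration: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Error attribution and sensorimotor recalibration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`recalib` analyses visuomotor rotation experiments with alternating
*feedback* and *perceptual probe* trials, where the scientific question is
how much of a visual prediction error a subject attributes to internal
causes, and how strongly that internally attributed component recalibrates
the internal prediction of the visual consequences of the next movement.
This vignette documents the generative model behind the synthetic cohort,
the measurement definitions, the numerical choices, and the places where
the design was genuinely open and a decision had to be made.

## The generative model

A cohort is defined by `generator_params()`. Per subject and trial pair:

1. **Feedback trial.** The motor direction is drawn uniformly from
   `mpd_range_deg` (default [10°, 70°] — free choices in this paradigm
   concentrate in the upper-right sector between the subjective rightward
   and anterior directions). The feedback rotation m comes from a discrete
   uniform distribution over {0°, ±5°, ±10°, ±20°, ±40°}. The perceived
   pointing direction is
   `PPD_fb = offset_fb + w(|m|)·m + ε`, with `ε ~ N(0, σ²)` and w the
   attribution-weight profile. The *realised* attributed component
   `w(|m|)·m + ε` is carried to the next trial.
2. **Probe trial** (`coupling_mode = "attributed"`, the default). If
   `|m| > deadzone_deg`, the percept is
   `PPD_pp = offset_pp + (g(|m|)/w(|m|)) · (w(|m|)·m + ε_fb) + ε_pp`;
   otherwise only `offset_pp + ε_pp`. Taking expectations gives the
   per-amount condition mean `g(|m|)·m`, i.e. the relative-recalibration
   profile g; conditioning on m gives a within-amount regression of probe
   on feedback percepts with slope `g/w`. Both the condition means and the
   trial-by-trial correlation therefore emerge from one mechanism — the
   probe percept tracks the *realised* attributed error of the specific
   preceding trial, not just its expectation. A mean-only model could
   reproduce the condition means but no within-amount correlation, which is
   precisely the phenomenon of interest.
3. **Motor adaptation.** The probe-trial motor direction is shifted by
   `−motor_adapt_gain · g(|m|) · m`: the movement compensates for the
   recalibrated visual consequence. With the default gain of 1 this
   produces the negative condition-level correlation between mean motor
   direction and mean percept that the analysis tests for.
4. **Trajectories.** Each trial gets raw fingertip samples: a minimum-jerk
   radial profile out to slightly beyond the 9° instructed amplitude, a
   sinusoidal lateral bow whose magnitude (SD `curvature_noise_sd_deg`,
   default 0.5°) equals the maximum chord deviation, and a partial straight
   return. The trial's recorded MPD is the direction *fitted to this
   trajectory*, and EPD is constructed as MPD + PPD, so the generative and
   analytic chains agree exactly and the analysis adds no hidden noise.

A second coupling mode, `"uniform"`, sets
`PPD_pp = offset_pp + β·PPD_fb + ε` for all trials regardless of amount.
It exists to validate the trial-by-trial regression machinery: the mean
per-subject OLS slope must recover β.

### Defaults and what they assume

| parameter | default | rationale |
|---|---|---|
| `n_subjects`, `n_pairs` | 11, 180 | reference cohort size of the paradigm |
| `attribution_weight_by_amount` | .54/.57/.38/.19 | decreasing internal attribution with error size |
| `recal_gain_by_amount` | 0/.20/.14/.07 | deadzone at 5°, then decreasing relative recalibration |
| `deadzone_deg` | 5 | errors at or below it induce no recalibration |
| `perceptual_noise_sd_deg` | 4 | *assumption*: not an observable of the paradigm; chosen so single-trial weight estimates scatter with an SD of roughly 0.4 at ±10°, comparable to real trial-level histograms |
| `mpd_range_deg` | [10, 70] | *assumption*: uniform is a simplification of the empirical direction histograms |
| `offset_fb_deg`, `offset_pp_deg` | 0 | constant percept offsets exist in real data; they default to 0 but are configurable because the offset-correction stage must be exercised |
| `motor_adapt_gain` | 1 | full expression of recalibration in the next movement |
| `invalid_rate` | 0 | violations (short amplitude, curvature, velocity artefact, missing estimate) are injected only on request, to test the filters |

The perceptual noise is Gaussian and homoscedastic across conditions. Real
estimation noise may scale with eccentricity or attention; none of the
analyses here depend on that distinction, but parameter-recovery results
should be read as "the pipeline is unbiased under the stated model", not as
evidence about real noise structure.

## Kinematics and filtering

* The **outward segment** runs from the first sample to the first sample of
  maximal radial distance (earliest maximum on ties).
* The **motor pointing direction** is an orthogonal regression through the
  starting point: the first principal axis of the uncentred second-moment
  matrix, orientation resolved toward the endpoint. Orthogonal rather than
  y-on-x regression because the measure must be symmetric in x and y, must
  not degenerate near vertical movements, and the start point is physically
  anchored at the origin. Degenerate inputs (all samples at the origin,
  zero spatial variance, coincident chord endpoints, non-increasing
  timestamps) are rejected with errors, not guessed at.
* **Exclusion rules**, applied in order: amplitude below half the
  instructed amplitude → invalid; missing estimate → invalid; maximum chord
  deviation above 2.25° → excluded (online corrections); peak
  finite-difference speed above 120°/s → excluded (tracker artefacts; no
  smoothing, since smoothing would hide exactly these artefacts). All
  thresholds are strict inequalities, so boundary values are retained.
  Finally, probe trials whose immediately preceding feedback trial is not
  valid are discarded, because their interpretation depends on that trial.
  Except for this last rule the order is immaterial to the final valid set.
* Angles are plain real numbers in degrees; no modular wrap-around is
  applied in differences, as all task directions lie far from the ±180°
  seam.

## Measures

Offset correction subtracts, per subject and condition, the mean PPD of the
veridical reference trials (feedback trials with m = 0; probe trials
preceded by m = 0), computed on valid trials only and after kinematic
filtering — the order is a package decision, made so that reference means
are never contaminated by movement artefacts. Quotients (weight,
recalibration) are computed per trial and then averaged within subject per
cell, rather than as a quotient of means: the trial-level distribution of
the weight is itself an object of analysis (unimodality screen), so it must
exist. Veridical trials never enter quotients; they serve as offset
references and as the 0° condition of the motor and regression analyses.
Pooling across orientations concatenates counterclockwise values with
sign-flipped clockwise values for raw PPDs; quotients are already
sign-normalised and concatenate unchanged.

## Inference

* **Repeated-measures ANOVA** (2 orientations × 4 amounts, and one-way
  designs) is implemented as the standard within-subject sums-of-squares
  decomposition, each effect tested against its own effect-by-subject
  interaction. Mauchly's test (with the second-order Box term of the
  chi-square approximation, matching the base-R convention) is run per
  multi-level effect on orthonormal contrast scores; the Greenhouse–Geisser
  epsilon is always reported and the corrected p-value is adopted whenever
  Mauchly rejects at α = .05. That trigger rule is a package decision — the
  convention of reporting corrected dfs only where sphericity fails.
* **Planned contrasts** are one-tailed by design: the a-priori ordering is
  that both quotients decrease with increasing amount, and that
  correlations and quotients are positive. Bonferroni families follow the
  "within each measure" rule: 3 for the sequential neighbour contrasts,
  4 for the per-amount tests against zero, and the number of amount
  conditions for the per-amount regression aggregates.
* **Trial-by-trial regressions** are OLS per subject; per-amount analyses
  are run per signed manipulation and the coefficients averaged across the
  two orientations within subject. Per-subject correlation coefficients are
  aggregated as raw arithmetic means with standard errors — no Fisher
  transform — because the mean-± SE convention on raw r is the field's
  reporting convention for this quantity, and it is the quantity the
  half-normal Bayes factor consumes. Per-subject significance is read at
  α = .05 uncorrected, two-sided.
* **Bayes factors** follow the half-normal calculator convention: the
  likelihood `N(observed mean; θ, SE)` is integrated against a half-normal
  prior on θ ≥ 0 with mode 0 and SD 0.5 (appropriate for correlation-scale
  effects) and divided by the likelihood at θ = 0. The integral uses
  adaptive quadrature at 1e-8 relative tolerance, well inside the 1e-6
  documentation target; B > 3 and B < 1/3 mark substantial evidence.
* **Masson–Loftus normalisation** removes each subject's mean deviation
  from the grand mean before error bars are computed, leaving condition
  means untouched; summaries report both raw and normalised SEs, labelled.

## Validation strategy and problem sizes

Every estimator is checked against an independent oracle (angle-space
minimisation for the line fit, pointwise recomputation for the chord
deviation, normal equations for OLS, the eigenvalue formula for epsilon,
trapezoid quadrature for the Bayes factor, the multivariate-model ANOVA in
`car` for the full decomposition), and the full pipeline is checked by
parameter recovery: cohorts generated with known w and g profiles must
return them within three across-subject standard errors. Unit tests use
small cohorts (2–6 subjects, 20–150 pairs) chosen to keep the default test
run fast; the end-to-end checks use the full 11 × 180 reference cohort.
With the default noise of 4°, the across-seed SD of the pooled weight at
±5° is about 0.03 (it shrinks roughly with 1/amount for larger rotations),
which sets the honest resolution of any single recovery run.

## Known limitations

* The generator is a statistical emulator, not a biomechanical model: no
  reaction/movement-time structure, no online feedback corrections in
  feedback trials (the paradigm finds none), no eye movements, no learning
  drift across the session. Passing recovery tests validates the analysis
  chain under these assumptions, not the assumptions themselves.
* Probe-trial coupling is linear in the realised attributed component;
  saturation or asymmetries between orientations are not modelled (the
  orientation factor of the ANOVA exists precisely to detect them in real
  data).
* The per-amount Bayes factors on synthetic cohorts can be far more extreme
  than in small real samples, because the generator's coupling is exactly
  linear and homoscedastic.
* Exact reproduction of subject-level numbers from real recordings is out
  of reach by construction — no raw data ship with the package — so the
  acceptance experiment is parameter recovery under the reference
  conditions plus analytic checks, not a re-analysis.
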