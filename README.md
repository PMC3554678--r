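# recalib

Trial-by-trial analysis of causal error attribution and sensorimotor
recalibration in visuomotor rotation experiments.

## The problem

When we move, the nervous system predicts the sensory consequences of the
movement from internal signals (efference copies, corollary discharge). A
mismatch between the predicted and the actual sensory input — a *prediction
error* — can stem from an external disturbance or from a change inside the
sensorimotor system itself, and only the internally caused part should drive
recalibration of the internal predictions.

The paradigm this package analyses probes that mechanism with alternating
trial pairs. In *feedback trials*, subjects point in freely chosen directions
while the visual feedback about the fingertip is rotated around the start
point by an unpredictable angle m drawn uniformly from
{0°, ±5°, ±10°, ±20°, ±40°}. After every movement the subject reports the
direction they believe they moved (estimated pointing direction, EPD), which
together with the executed direction (motor pointing direction, MPD, fitted
to the raw trajectory) gives the *perceived pointing direction*

    PPD = EPD − MPD .

In the interleaved *perceptual probe trials* no feedback is shown, so the
percept reflects the current internal sensory prediction. Two quotients
carry the scientific content (both offset-corrected within subject against
veridical-feedback reference trials):

* **relative weight of visual information** `w = PPD_feedback / m`
  — the share of the prediction error attributed to internal causes
  (1 = fully internal, 0 = fully external);
* **relative recalibration** `PPD_probe / m_prev`
  — the single-trial perceptual aftereffect of the preceding error.

The package implements the full analysis chain — trajectory line fits
(orthogonal regression through the start point), curvature/velocity/amplitude
exclusion filters, offset correction, orientation pooling,
repeated-measures ANOVA with Mauchly/Greenhouse–Geisser sphericity handling,
planned one-tailed Bonferroni-corrected contrasts, per-subject trial-by-trial
regressions, half-normal-prior Bayes factors, Shapiro–Wilk unimodality
screening, Masson–Loftus within-subject error bars — plus a seeded
synthetic-cohort generator whose attribution weights, recalibration gains,
error deadzone and motor-adaptation coupling are known, so every stage can be
validated by parameter recovery.

## Worked example

Generate the reference cohort (11 subjects × 180 feedback/probe pairs,
attribution weights 0.54/0.57/0.38/0.19 at 5/10/20/40°, recalibration gains
0/0.20/0.14/0.07 with a 5° deadzone, perceptual noise SD 4°) and run the
whole pipeline:

```r
library(recalib)
report <- run_pipeline(pipeline_config(generator_params(seed = 42)))
print(report)
#> <recalib_report>
#>
#> Relative weight of visual information (pooled, mean +- SE across subjects):
#>     5 deg: 0.523 +- 0.042
#>    10 deg: 0.532 +- 0.015
#>    20 deg: 0.366 +- 0.010
#>    40 deg: 0.186 +- 0.006
#>
#> Relative recalibration (pooled):
#>     5 deg: -0.053 +- 0.036
#>    10 deg: 0.218 +- 0.020
#>    20 deg: 0.131 +- 0.007
#>    40 deg: 0.076 +- 0.004
#>
#> Trial-by-trial regression (probe ~ preceding feedback):
#>   mean r = 0.458 +- 0.016; mean slope = 0.307 +- 0.013; 11/11 subjects significant
#>   Bayes factors by amount: B(0)=0.35, B(5)=0.04, B(10)=29305059313.35, B(20)=36529882.00, B(40)=184878782.95
#>
#> Motor/percept condition-level correlation: r(7) = -0.86, p = 0.00303
#> Unimodality screen: 42 of 44 cells tenable
```

Reading the output: the estimated visual weights recover the generating
profile (high for small errors, falling to ~0.19 at 40°); the relative
recalibration is indistinguishable from zero at the 5° deadzone and
decreases from ~0.2 at 10° to ~0.07 at 40°; probe-trial percepts are
positively coupled to the preceding feedback-trial percepts (and the
per-amount Bayes factors separate amounts above the deadzone, B ≫ 3, from
0° and 5°, B < 1); probe-trial *motor* directions correlate negatively with
the recalibrated percepts (motor adaptation); and the per-trial weight
distributions are unimodal in almost all subject × amount cells.

`run_pipeline()` also accepts externally recorded data via
`trials = read_trials("trials.csv")` (optionally with raw trajectories,
`samples = read_samples("samples.csv")`, from which kinematics are
recomputed), and `out_dir =` writes the trial table, summary tables and a
JSON summary. A thin command-line wrapper with `simulate`, `analyze` and
`reproduce` subcommands is installed at `inst/scripts/recalib-cli.R`.

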