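# deltatrack

Longitudinal natural-history modelling of EEG delta power for Angelman
syndrome (AS) biomarker analysis.

Delta-band (2–4 Hz) power in the scalp EEG is elevated in AS and tracks
disease severity, but it varies widely between individuals and falls with
age, so a single cross-sectional measurement is a weak instrument for
detecting a treatment response. deltatrack implements the longitudinal
alternative used in AS natural-history work: predict each subject's delta
power at a later visit from its value at an initial visit, the subject's
age, and the elapsed time, with a per-subject random intercept,

δ<sub>subsequent</sub> = β₀ + β₁·δ<sub>initial</sub> +
β₂·log₁₀(age<sub>initial</sub>)·IVI + b<sub>subject</sub> + ε,
  b ~ N(0, σ<sub>b</sub>²), ε ~ N(0, σ<sub>e</sub>²),

where IVI is the inter-visit interval. Deviations from this expectation —
residuals, with the convention **predicted − observed**, so that
delta-lowering treatment gives *positive* residuals — are the
treatment-sensitive quantity.

The package covers the full path from raw signal to inference:

* **Spectral estimation** — relative delta power from scalp EEG
  (average-re-referenced posterior channels, 1 s Hanning windows, summed
  2–4 Hz over 1–50 Hz power), and absolute delta activity from mouse
  visual-cortex LFP (DPSS multitaper, peak of the 1–5 Hz spectrum,
  hemisphere-averaged, after automatic noisy-channel exclusion).
* **Stability curves** — epoch-resampling SEM of the delta estimate versus
  amount of data (random or contiguous epochs).
* **The natural-history model** — ML mixed-effects fit, predictions,
  residuals, leave-one-subject-out and leave-one-week-out cross-validation.
* **Trial power simulation** — two-arm bootstrap with an injected offset on
  the treated arm's subsequent-visit delta, one-sided residual t-test, power
  surfaces over offsets × group sizes.
* **Mouse treatment-effect detection** — surrogate week-2 baselines for
  mice lacking pre-treatment recordings, per-week median-residual effect
  distributions (10,000 resamples), and a mouse-level permutation null
  with calibrated tail p-values; cross-age contrasts included.
* **Expression coupling** — slope resampling relating model residuals to
  relative *Ube3a* mRNA.
* **Synthetic generators** — EEG with programmed relative delta power and
  human/mouse/expression cohorts generated at the study design sizes with
  known ground truth, so every stage is testable end to end.
* **I/O and pipeline** — a minimal EDF reader/writer, schema-checked CSV
  tables, JSON reports, a YAML-configured `run_pipeline()`, and a thin CLI
  (`inst/cli/deltatrack.R`).

## Worked example

Estimate delta power from a synthetic recording, fit the natural-history
model on a synthetic 56-subject cohort, cross-validate, and size a trial:

```r
library(deltatrack)

rec <- make_synthetic_eeg(0.35, duration_s = 120, fs = 256, seed = 42)
relative_delta_power(rereference_average(rec))
#> <delta_estimate> mode=relative value=0.3441 (unitless), 120 interval(s), SEM 0.00613

cohort <- make_human_cohort(seed = 1)    # 56 subjects, 204 visits
fit <- fit_natural_history(cohort$pairs)
fit
#> Natural-history model (ML, 148 pairs / 56 subjects, ages in years)
#>             term estimate      se  df      t         p    ci_lo    ci_hi
#>        intercept   0.2298 0.02774 144  8.283 7.558e-14  0.17490  0.28460
#>    delta_initial   0.5196 0.06010 144  8.646 9.428e-15  0.40080  0.63840
#>  log10_age_x_ivi  -0.0332 0.00547 144 -6.070 1.076e-08 -0.04402 -0.02239
#> sigma_b = 0.03466, sigma_e = 0.08778, RMSE = 0.09421, AIC = -271.54

cross_validate(cohort$pairs)
#> Cross-validation (leave-one-subject-out, 56 folds)
#> pooled RMSE = 0.09611 (in-sample 0.09421)

power_curve(cohort$pairs, fit, offsets = seq(0, 0.1, by = 0.01),
            group_sizes = c(50, 150), n_sims = 1000, seed = 7)
#> <power_curve> alpha=0.05, 1000 sims/cell
#> smallest offset with power >= 0.8, per group size:
#>   n=50: 0.05
#>   n=150: 0.03
```

The delta estimate recovers its programmed target (0.35) within its SEM;
the fitted coefficients sit within sampling error of this cohort's
generating values (a positive initial-delta slope near 0.5 here, a negative
age×IVI interaction); and with ~0.09 residual SD the design reaches 80%
power near a 0.05 reduction in relative delta power at 50 subjects per arm
(0.03 at 150 per arm).

Detecting an ASO treatment effect in a synthetic mouse cohort (15 treated,
26 control, true injected effect 1e-3 mV²/Hz from week 2 on):

```r
mouse <- make_mouse_cohort(seed = 1)
mfit <- fit_natural_history(mouse_control_pairs(mouse$visits),
                            units = "weeks")
eff <- treatment_effect_by_week(mouse$visits, mfit, n_resamples = 2000,
                                seed = 2)
eff
#> <treatment_effect_by_week> 2000 resamples
#>  week effect_mean     ci_lo     ci_hi n_treated n_control
#>     3   0.0008768 0.0008350 0.0009108        15        26
#>     4   0.0007732 0.0007368 0.0008140        15        26
#>     5   0.0011581 0.0011247 0.0011935        15        26
#>     6   0.0008068 0.0007641 0.0008467        15        22
#>     7   0.0013033 0.0012578 0.0013388        15        17
#>     8   0.0009969 0.0009581 0.0010353        15        12

permutation_null(mouse$visits, mfit, n_resamples = 2000, observed = eff,
                 seed = 3)$p
#>      3      4      5      6      7      8
#> 0.0005 0.0005 0.0005 0.0005 0.0005 0.0035
```

The per-week effect estimates bracket the injected 1e-3 mV²/Hz and every
week is significant against the mouse-level permutation null — a treatment
effect detectable through week 8 even though treated mice have no
pre-treatment baseline.

## Command-line interface

```sh
Rscript inst/cli/deltatrack.R simulate --kind human --seed 4 --out sim
Rscript inst/cli/deltatrack.R fit --pairs sim/pairs.csv --units years
Rscript inst/cli/deltatrack.R delta --edf recording.edf \
    --channels O1,O2,P3,Pz,P4 --mode relative
Rscript inst/cli/deltatrack.R power --pairs sim/pairs.csv \
    --sizes 25,50,100,150 --offsets 0:0.1:0.002 --sims 2000 --seed 1
Rscript inst/cli/deltatrack.R mouse-effect --visits mice.csv \
    --resamples 10000 --seed 1
```

## Documentation

The methods vignette (`vignettes/natural-history-delta-power.Rmd`) explains
the model and its assumptions, the spectral and resampling conventions, the
synthetic-generator design (including what it deliberately does not
emulate), numerical choices, and known limitations.
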