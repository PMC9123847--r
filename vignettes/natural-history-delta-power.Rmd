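---
title: "Modelling the natural history of EEG delta power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the natural history of EEG delta power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Delta-band (2--4 Hz) EEG power is elevated in Angelman syndrome and tracks
disease severity, which makes it an attractive non-invasive biomarker for
trials of UBE3A-restoring therapies such as antisense oligonucleotides
(ASOs) directed at the *Ube3a* antisense transcript. The obstacle is
variability: delta power differs several-fold between individuals and
declines with age, so a cross-sectional comparison of treated and untreated
groups at a single time point has little power. deltatrack implements the
longitudinal alternative: model each individual's *expected* delta power at
a later visit from where they started, how old they were, and how much time
elapsed -- then treat deviations from that expectation as the
treatment-sensitive signal.

# The natural-history model

The central object is a linear mixed-effects model on longitudinal visit
pairs:

$$\delta_{subsequent} = \beta_0 + \beta_1\,\delta_{initial}
  + \beta_2\,\log_{10}(\mathrm{age}_{initial})\cdot \mathrm{IVI}
  + b_{subject} + \varepsilon,$$

with $b \sim N(0, \sigma_b^2)$ a subject-level random intercept and
$\varepsilon \sim N(0, \sigma_e^2)$ residual noise. IVI is the inter-visit
interval, in the same unit as age (years for human cohorts, weeks for
mice). The model assumes the age dependence enters only through the
$\log_{10}(\mathrm{age})\times$IVI interaction (no effect of age when no
time elapses), linearity in the initial value, and Gaussian, homoscedastic
noise. Estimation is by maximum likelihood via lme4 (REML available but not
the default); Wald t-tests use residual degrees of freedom
($n_{pairs} - 4$), with Satterthwaite degrees of freedom available through
lmerTest. Noise-free (degenerate-variance) inputs fall back to ordinary
least squares with $\sigma_b = 0$, which is the exact limit.

**Residual sign convention.** Throughout the package, residual =
*predicted minus observed*. An effective treatment is expected to *lower*
delta power, so effective treatment produces *positive* residuals. This is
the opposite of the usual regression convention and is chosen so that
"larger residuals in the treated group" reads as "treatment effect".

Model validation uses leave-one-subject-out cross-validation (humans and
mice) and leave-one-week-out cross-validation (mice, whose visits fall on a
weekly grid); held-out residuals are always population-level (random
intercept at zero), since a new trial subject is unseen by the model.

# Spectral conventions

Two estimators feed the model:

* **Relative delta power (human scalp EEG).** Posterior channels (O1, O2,
  P3, Pz, P4 by convention) are re-referenced to their instantaneous group
  average. Power spectra are computed on non-overlapping 1 s windows
  (1 Hz resolution, Hanning taper, each window demeaned before tapering).
  Per window, summed power in the delta bins is divided by summed power in
  the total band, and the per-window ratios are averaged. With 1 Hz
  resolution, "2--4 Hz" is taken as the three bins $\{2,3,4\}$ Hz inclusive
  and "1--50 Hz" as the fifty bins $\{1..50\}$ inclusive; both bands are
  configurable. Channels are combined as a ratio of channel averages (the
  default), with mean-of-per-channel-ratios available
  (`channel_combine = "average_of_ratios"`); on typical posterior montages
  the two differ by far less than the between-visit variability the model
  absorbs. Wake staging is an input (a sidecar file of intervals), never
  computed: only windows fully inside wake intervals are analysed.

* **Absolute delta activity (mouse visual-cortex LFP).** DPSS multitaper
  spectra (5 tapers, time-bandwidth product 3, 5 s windows with 1 s
  overlap) on the last 10 minutes of each session, averaged over windows
  and then across hemispheres; the estimate is the *peak* of the averaged
  spectrum between 1 and 5 Hz inclusive, in mV²/Hz. Channels whose log
  total power deviates from the cohort median by more than 3 robust
  z-units, or that sit pinned at a rail value for 0.1 s or more, are
  excluded first (`exclude_noisy_channels()`; the thresholds are
  configurable and the rule is this package's own, standing in for an
  unpublished rejection step). One caveat follows from the normalization:
  multitaper power scales depend on implementation conventions, so absolute
  values are comparable within this package but not directly against other
  toolboxes.

The DPSS tapers themselves are computed from the classical symmetric
tridiagonal eigenproblem -- dense for short windows, Sturm-sequence
bisection plus inverse iteration for long ones -- and are validated in the
test suite against reference values to seven decimal places.

# Stability of the estimate

`sem_random_epochs()` and `sem_contiguous_epochs()` quantify how much data
a stable delta estimate needs: they resample 1 s epochs (without
replacement) or contiguous runs (uniform random start times, no
wraparound) from a long recording and report the empirical SEM -- the
standard deviation across resampled means -- plus empirical 95% bounds. The
resampling definition matters: under circadian drift an analytic
$s/\sqrt{n}$ SEM is wrong for contiguous samples, and the two curves
deliberately diverge there. Defaults follow the procedure the curves are
meant to reproduce: 1000 repetitions per sample size.

# Trial power by offset injection

`power_curve()` estimates the power of a two-arm trial design: sample
longitudinal pairs with replacement for a control and a treatment arm,
subtract a fixed offset from the treatment arm's subsequent-visit delta
(clamped at zero, with clamps counted), compute population-level residuals
under the *fixed* pre-fitted natural-history model, and compare arms with a
one-sided Welch t-test at $\alpha = 0.05$. The model is fitted once on the
untreated pool and held fixed -- it is the measurement instrument, not part
of the simulated trial; a per-simulation refit is deliberately not the
default. Defaults: offsets 0--0.1 in steps of 0.002, 25/50/100/150
subjects per arm, 2000 simulations per cell. The closed-form two-sample
noncentral-t power is the implementation oracle: with a Gaussian residual
pool the simulated power tracks it within 0.03, and at a residual SD of
0.09 the design reaches 80% power at offsets near 0.046 (50 per arm) and
0.027 (150 per arm).

# Mouse treatment effects without pre-treatment baselines

Electrode implantation precludes dosing after recording starts, so treated
mice have no pre-treatment delta measurement. The package follows the
surrogate-baseline strategy: for each target visit, draw one week-2
(youngest) control observation at random as the initial visit -- excluding
the same mouse when it is in the pool -- predict the target from it, and
take the residual. The per-week treatment effect is the difference in
median residuals (treated minus control), re-estimated over many fresh
baseline draws (default 10,000) to give an effect distribution and
empirical 95% bounds. Week 2 serves as the initial visit only; no effect is
reported there.

Significance comes from a mouse-level permutation null: pseudo-treated and
pseudo-control groups of the original sizes are drawn without replacement
from the pooled mice (a mouse keeps one pseudo-label across all weeks), and
the whole effect computation is repeated per relabeling. Two p-values are
offered. The default is the empirical tail probability of the observed mean
effect under the null distribution of relabeled effects -- the standard,
calibrated permutation p (each relabeled effect averages a few inner
baseline draws so that its draw-noise footprint matches the observed
statistic's). The alternative (`p_method = "t_test"`) compares the observed
and null effect *distributions* directly with a one-sided two-sample
t-test; because both distributions contain thousands of resampled values,
this inflates significance and is provided for fidelity to the procedure it
reproduces, not recommended for inference.

Prediction for treated mice is population-level by default (a treated mouse
is unseen by the control-fitted model). An empirical-Bayes option
(`mode = "empirical_bayes"`) instead shrinks the drawn baseline's deviation
from the pool mean into a subject intercept; it sharpens predictions
slightly when $\sigma_b$ is large but ties the residual to the particular
draw, so the calibrated default is population-level.

`cross_age_contrast()` applies the same machinery to groups observed at
*different* weeks -- the model's age/IVI adjustment is what makes that
comparison meaningful, and a naive t-test on raw deltas is reported
alongside for contrast.

# Expression coupling

`residual_mrna_slopes()` regresses surrogate-baseline residuals on relative
*Ube3a* mRNA (ordinary least squares with intercept, no weighting) over the
mice with both measurements -- the published design has 8 control and 4
treated mice measured at week 8 against week-7 residuals. The mice are
fixed; the 1000-repetition resampling varies only the week-2 baseline
draws, exactly mirroring the procedure it implements. Control and treated
mice enter one pooled regression by default. One subtlety the tests pin
down: when mRNA is an exact affine function of the true deviation,
$\mathrm{mrna} = a + b\cdot\mathrm{dev}$, the population slope of residual
on mRNA is $1/b$ (the noise is in the response, so there is no
attenuation).

# The synthetic generators

Every pipeline stage is testable without access to clinical data because
the generators emit data *with known ground truth* at the study's design
conditions.

**Synthetic EEG** (`make_synthetic_eeg()`) is a sum of constant-modulus,
random-phase sinusoid processes on the integer frequencies 1--50 Hz,
renewed every second so that 1 s analysis windows are independent
realizations. A Hann-tapered bin-centred tone splits its power
$1/6 : 2/3 : 1/6$ over the centre and adjacent bins; the per-frequency
variances are solved against that leakage kernel so the expected relative
delta power equals the programmed target exactly. Channels carry
independent phases, so average re-referencing attenuates all frequencies
equally and preserves the target in expectation. What the generator does
*not* emulate: EEG morphology (spindles, artifacts, 1/f background) -- only
band-power statistics -- so passing recovery tests validates the
estimators' arithmetic, not robustness to real-world artifact.

**Human cohort** (`make_human_cohort()`): 56 subjects, 204 visits (2--13
per subject), first-visit ages log-uniform on 0.89--32.5 years, IVIs
log-uniform from 2 days to 7 years. Subsequent visits are generated from
the subject's *first* visit under the natural-history equation, which keeps
the regressors exogenous to the random intercept and makes maximum-
likelihood recovery unbiased. Generating coefficients default to the
published fixed effects (0.25, 0.43, $-0.03$); $\sigma_e = 0.09$ anchors to
the published cross-validated RMSE; $\sigma_b = 0.05$ is an assumption (the
inter-subject spread is not separately reported). The initial-visit delta
marginal -- never part of the longitudinal model -- is a truncated normal
with mean $0.55 - 0.15\log_{10}(\mathrm{age})$, SD 0.12, clipped to
$[0.05, 0.95]$, chosen to span the plotted range of observed cohorts while
keeping clipping below 1%.

**Mouse cohort** (`make_mouse_cohort()`): groups of 28 wild-type controls,
26 AS controls and 15 AS ASO-treated mice, weekly visits from
post-treatment week 2 to 8 (ages week + 5, dosing at P35). Control mice
carry 4--7 contiguous weekly visits allocated 12/5/5/4, which reproduces
the published all-pairs design exactly (6--21 pairs per mouse, 401 pairs
total). Because every visit serves as both response and regressor in the
all-pairs design, *no* trajectory satisfies the pairing model exactly;
instead the mean weekly trajectory is solved (minimum-norm Gauss--Newton
over the weekly means) so that the population regression *estimand* --
cross-moments including the regressor noise $\sigma_b^2 + \sigma_e^2$ and
the shared-intercept covariance $\sigma_b^2$ -- equals the generating
coefficients. The solve starts from a first-week-anchored trajectory with a
steepened decline, keeping the solution positive, on the observed mV²/Hz
scale, and falling two-to-three-fold across the study weeks as AS control
mice do. Variance defaults $\sigma_b = 2\times10^{-4}$,
$\sigma_e = 4\times10^{-4}$ put the population residual SD at the published
full-model RMSE ($\approx 4.5\times10^{-4}$ mV²/Hz). Treated mice are
shifted down additively by `treatment_effect` (default $10^{-3}$ mV²/Hz,
the scale of the published per-week effects) at every observed week.

**Expression** (`make_expression()`): relative mRNA is a group baseline
(wild-type 1.0, AS 0.22, matching the published group means) plus a
coupling slope times the mouse's true deviation from natural history, plus
Gaussian noise, clipped at zero; the default coupling (280 per mV²/Hz)
lands treated mice near the published ~0.5 relative expression.

# Numerical choices and degenerate inputs

* Windows are demeaned before tapering (keeps DC bleed out of the 1 Hz
  bin); partial trailing windows are dropped.
* Windows with zero total power are dropped and counted; all-dropped is an
  error. Offset injection clamps delta at zero and counts clamps.
* The PSD normalization satisfies Parseval (integrated PSD equals the
  tapered window's variance), so band sums are physically interpretable.
* Mixed fits that fail or produce degenerate covariance (noise-free data)
  fall back to OLS with $\sigma_b = 0$; singular-fit warnings from the
  optimizer are suppressed as they are expected at that boundary.
* All resampling machinery accepts an explicit seed, consumes no RNG
  outside it (the DPSS solver uses deterministic start vectors for exactly
  this reason), and sorts inputs by subject/mouse id internally so results
  are invariant to input row order.
* Duplicate same-age visits for a subject and unmatched expression records
  are errors, not silent drops.

# What the tests do and do not establish

The test suite validates: exact tone/white-noise spectral oracles;
taper values against an independent reference; unbiased recovery of the
human generating coefficients over 200 replicate cohorts (each within
three Monte-Carlo standard errors); power-curve agreement with the
closed-form noncentral-t oracle within 0.03 and type-I calibration at
$\alpha$; mouse null p-value uniformity (Kolmogorov--Smirnov over 500
replicate null cohorts at 1000 resamples) and injected-effect recovery
within 10%; recovery of the mouse age:IVI interaction coefficient over 200
cohorts; and SEM $\propto 1/\sqrt{n}$ scaling for iid stability input.
Problem sizes in the routine suite are scaled to the information they need
(hundreds of resamples where distributions are compared, thousands where
tail probabilities are asserted); the published resampling counts (10,000
and 1000) remain the function defaults.

Known limitations, stated rather than hidden:

* The per-interval ratio estimator has a small negative bias of order one
  over the channel count (about $-0.01$ at the five-channel montage)
  arising from interference between adjacent frequencies under the ratio
  nonlinearity; it is invisible at typical recording lengths but resolvable
  on multi-hour synthetic recordings.
* In the mouse all-pairs design the initial-delta coefficient is only
  weakly identified from trajectory data (measurement noise on the
  regressor attenuates it; the shared intercept pushes the other way), and
  its mean recovered value sits about 15% below the generating value at the
  default variance components. The age:IVI interaction -- the coefficient
  the analysis interprets -- recovers without measurable bias.
* Real EEG brings artifacts, staging uncertainty and non-stationarity that
  the generators deliberately do not model; green tests certify the
  statistical machinery, not robustness to those.

# Reproducing the headline numbers

`scripts/acceptance.R` regenerates the synthetic cohorts from a seed and
recomputes the recovered human coefficients, the simulated trial power at
the 0.046 offset with 50 subjects per arm, and the recovered mouse
interaction coefficient; see the README for invocation.
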