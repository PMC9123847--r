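Package: deltatrack
Title: Longitudinal Natural-History Modelling of EEG Delta Power
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to track delta-band (2-4 Hz) EEG power as a longitudinal
    biomarker in Angelman syndrome. Implements spectral estimation of relative
    delta power from scalp EEG (Hanning-tapered 1 s windows) and of absolute
    delta activity from mouse visual-cortex local field potentials (DPSS
    multitaper), epoch-resampling stability curves, a random-intercept
    natural-history model predicting delta power at a subsequent visit from
    the initial visit, age, and inter-visit interval, bootstrap clinical-trial
    power simulation with offset injection, a surrogate-baseline resampling
    and permutation-null detector for treatment effects in mouse cohorts, and
    slope resampling relating model residuals to Ube3a mRNA expression.
    Synthetic-data generators with known ground truth make every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    lmerTest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
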