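Package: neolus
Title: Quantitative Lung Ultrasound Analysis of Neonatal Lung Aeration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying lung aeration after birth from lung
    ultrasound (LUS) clips and physiological recordings. Implements the
    pixel-intensity coefficient-of-variation (CoV) estimator of the
    proportion of air in the lung (EPA), motion-frame exclusion and the
    linear CoV-to-EPA calibration; the ordinal LUS grading scale with
    backsliding and severe-backsliding event detection on longitudinal
    timelines; the alveolar-arterial oxygen difference (AaDO2) from
    arterial blood gases; breath segmentation and rate/variability/effort
    metrics from intrapleural and tracheal pressure traces; and the
    accompanying statistical plan (normality-gated test selection,
    per-timepoint rank tests with Bonferroni correction, random-intercept
    mixed models, lamb-adjusted regression, Dunnett block comparisons and
    paired-design power analysis). A synthetic-cohort generator emulates a
    two-group neonatal lamb study (control vs elevated lung liquid) with
    known ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tiff,
    lme4,
    lmerTest,
    multcomp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
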