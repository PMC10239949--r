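---
title: "Quantifying neonatal lung aeration from ultrasound, gas exchange and breathing traces"
author: "neolus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neonatal lung aeration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neolus)
```

## The problem

At birth the fetal lung is liquid-filled; gas exchange only becomes
possible as that liquid is cleared and replaced by air. Monitoring how far
and how fast a newborn's lungs aerate — in real time, at the bedside — is
what lung ultrasound (LUS) offers. Two readouts are in use:

* an **ordinal grade** in $\{0, 0.5, 1, 2, 3\}$ assigned from the artifact
  pattern of the image (hepatisation, a speckled pleural line, white-out,
  B-lines with some A-lines, pure A-lines), and
* a **continuous estimate**: the coefficient of variation of pixel
  intensity (CoV $= \sigma/\mu$ over regions of interest below the pleural
  line, away from rib shadows) rises as the lung aerates, and a linear
  calibration maps it to an *estimated proportion of air* (EPA) in
  $[0, 1]$.

This package implements the full analysis chain around these readouts:
clip quantification, longitudinal *backsliding* detection, the
alveolar-arterial oxygen difference (AaDO2) as the physiological
reference, breath metrics from pressure traces, and the statistical plan
that ties them together. Because no real dataset is distributed, a
synthetic-cohort generator with known ground truth stands in for the
animal study the design emulates: spontaneously breathing near-term lambs
with normal (control, n = 10) or elevated (EL, n = 9) lung liquid at
birth, imaged on a fixed schedule for four hours.

## Clip quantification

`pixelCov()` computes, for every retained frame and every ROI, the
**population** standard deviation of pixel intensity divided by the mean,
and averages over (frame, ROI) pairs. Two deliberate conventions:

* *Population (n) SD, not sample (n − 1).* The ROI is the entire pixel
  population under consideration; fixing the convention makes the
  statistic exactly reproducible. (Pooling all pixels into one population
  instead of averaging per-(frame, ROI) CoVs is available via
  `pool = TRUE`.)
* *ROIs are 0-based, half-open rectangles* stored in JSON, at least 64 px
  in area, fully inside the frame. Manual ROI drawing on real images is
  replaced by file-supplied ROIs (and generator-supplied ROIs for
  synthetic clips).

Because CoV is a ratio it is *exactly* invariant to multiplicative gain
changes; intensities are converted to floating point before any
statistics and no histogram preprocessing is applied (gain is fixed at
acquisition).

`detectMotionFrames()` excludes frames corrupted by movement: frame $i$ is
flagged when its mean absolute difference from the most recent *retained*
frame, normalised by the clip's global mean intensity, exceeds a
threshold (default 0.15; the exclusion criterion itself is a free
parameter — only the fact of exclusion is prescribed by the protocol the
package follows). Comparing against the last retained frame rather than
the literal predecessor prevents the frame after an isolated motion frame
from also being flagged.

`fitCalibration()` is ordinary least squares of reference EPA on CoV, and
`covToEPA()` applies the line and clamps to $[0, 1]$. The calibration
coefficients of the original imaging technique are not public, so the
package treats calibration as an input, fitted here on synthetic
reference clips.

## The synthetic cohort

`cohortConfig()` defines the study conditions; its defaults *are* the
emulated design and are not tuned per analysis.

* **Imaging schedule** (`defaultSchedule()`): one pre-breathing scan
  (encoded as a negative time), then every 2.5 min to 10 min after
  breathing onset, every 5 min to 30 min, every 10 min to 60 min, and
  every 20 min to 240 min. Blood gases follow their own schedule
  (`bloodGasSchedule()`): every 5 min to 30 min, every 10 min to 60 min,
  every 20 min thereafter.
* **Aeration kinetics**: each lung follows a saturating exponential
  $EPA(t) = EPA_{max}\,(1 - e^{-t/\tau})$ — the simplest form matching the
  observed trajectory shape; no functional form is prescribed anywhere, so
  this is a modelling choice. Defaults: $EPA_{max} = 0.95$,
  $\tau_{control} = 12$ min, $\tau_{EL} = 24$ min (the elevated-liquid
  group clears liquid half as fast), lamb-level random shift SD 0.05,
  per-lung offset SD 0.02, per-timepoint noise SD 0.04, everything clamped
  to $[0, 1]$. The between/within-lamb variance decomposition is not known
  empirically; these SDs are free parameters chosen to look like
  biological scatter, not estimates.
* **Backsliding injection**: a Poisson number of events per lamb (mean
  1.5), each depressing both lungs by a uniform draw from $[0.2, 0.5]$ at
  one randomly chosen post-onset timepoint — transient, one-timepoint
  drops on the scale the event definition targets.
* **Grade ground truth** derives from true EPA by fixed thresholds
  (defaults $<0.1 \to 0$, $<0.3 \to 0.5$, $<0.5 \to 1$, $<0.85 \to 2$,
  else 3). No published mapping from grade to air fraction exists; the
  thresholds are configuration.
* **Clip rendering** (`synthesizeLUSClip()`): multiplicative
  gamma-distributed speckle (shape 16, speckle CoV 0.25) on a structured
  background whose A-line band contrast grows with the air fraction while
  the inter-band field darkens slightly, so that ROI pixel CoV rises
  monotonically and approximately linearly with true EPA (measured
  calibration $R^2 \approx 0.98$ on the default geometry). Speckle is
  multiplicative because CoV is the quantity of interest and
  multiplicative noise keeps it gain-invariant; it is frozen across frames
  (real speckle is frame-correlated) so ordinary frames differ only by
  small additive noise while injected motion frames (global shift + blur)
  stand out. Rib shadows flank the lung zones. Grade-specific cues — the
  pleural-line appearance and a B-line stripe rendered just below the
  pleural line, above the ROIs so the CoV model is unaffected — feed the
  rule-based grader. This is a stylised phantom, not a wave-propagation
  simulation: passing tests show the *pipeline* recovers what the
  generator encodes, not that the method is validated on real tissue.
* **Blood gases**: true AaDO2 follows
  $AaDO2(t) = a + b\,(1 - \overline{EPA}(t)) +$ noise (defaults
  $a = 30$ mmHg, $b = 350$ mmHg, noise SD 20 mmHg, floored at 0), PaCO2 is
  drawn near 48 mmHg, FiO2 follows a support policy titrating towards a
  PaO2 of ~70 mmHg (clamped to $[0.21, 1]$), and PaO2 is back-computed so
  that `aado2()` on the emitted record reproduces the true AaDO2 exactly —
  a round trip the tests verify.
* **Breathing traces**: breath-by-breath synthesis of a smooth
  negative-going intrapleural deflection (so an amplitude-$A$ breath has
  swing $A$; a sinusoid of amplitude $A$ has swing $2A$) with lognormal
  length jitter. After a flow-change event the rate falls, breath-length
  CoV and swing rise — half effect for breaths 1–5, full effect for
  breaths 6–10, linear recovery to breath 30 — with default magnitudes
  −20.74 bpm, +0.31 CoV and +13.4 cmH2O, and an optional apnoea after the
  third post-event breath. The piecewise profile is a modelling choice
  that concentrates the response where the block analysis looks for it.

## Grading, agreement, backsliding

`medianGrade()` summarises ordinal grades as median (IQR) with
linear-interpolation quartiles (half-step medians such as 0.75 can appear
for even n). `percentAgreement()` is raw exact-match percentage — no kappa
by design.

`detectBacksliding()` marks a deterioration between *consecutive* scans:
a strict decrease in grade (half-steps count: the scale includes 0.5) in
either lung, or an EPA drop strictly greater than 0.2 in either lung. A
grade event is *severe* when the dropped lung lands at grade ≤ 1; an EPA
event is severe when the post-drop mean EPA across both lungs is below
0.6. Conventions the implementation fixes where the definitions are
silent:

* a pair can trigger *both* criteria and then yields two events (they are
  tabulated in separate columns);
* when only one lung is observed, "either lung" and the two-lung average
  reduce to that lung;
* a timepoint carrying neither grade nor EPA invalidates the pairs that
  touch it (skipped with a warning) — it does not bridge to the next
  usable scan;
* the strict inequalities carry a $10^{-9}$ guard so a drop of exactly
  0.2 stored in binary floating point does not count.

A 1000-timeline oracle suite checks the detector against a literal
double-loop restatement of the rules. `countBacksliding()` produces the
per-lamb and per-group table (proportion of lambs with ≥ 1 event, mean ±
SEM of counts) by trigger and severity.

`ruleBasedGrade()` is a demonstrator decision list over clip features
(pleural-line brightness and patchiness, B-line column fraction, A-line
periodicity score). Its thresholds are tuned to the synthetic phantom's
cues; it is not a substitute for expert grading of real images.

## Gas exchange

$$AaDO2 = FiO_2\,(P_{atm} - P_{H_2O}) - PaCO_2 / RQ - PaO_2$$

with $P_{atm} = 760$ mmHg and $RQ = 0.8$ by default. The saturated water
vapour pressure uses the Buck (1981) liquid-water formulation converted to
mmHg — chosen and frozen for reproducibility; it rounds to 52 mmHg at a
lamb body temperature of 39 °C, the anchor any conformant formulation must
hit. By default $P_{H_2O}$ is computed from each record's own temperature;
a fixed override (e.g. 52) is available since either reading of the
protocol is defensible. Negative AaDO2 values, which measurement noise can
produce, are returned as computed with a warning, never clipped.

## Breath analysis

`segmentBreaths()` detects inspiratory troughs on the intrapleural
channel (inspiration is a negative deflection there, which is why the
intrapleural, not tracheal, channel drives segmentation): light smoothing
(50 ms), local minima at least a prominence below the upper envelope
(default 25 % of the running 5th–95th percentile swing, floored at
1 cmH2O so sensor noise on a flat trace is never segmented), greedy
deepest-first selection with a minimum spacing (default 0.3 s). Breath
length is the trough-to-trough cycle period; cycles longer than 10 s are
reported as apnoeic gaps, not breaths. Trough detection is hand-written:
generic peak finders drop peaks on clean periodic signals with tied
heights, which respiratory traces produce routinely.

`respiratoryRate()` is $60/\overline{\text{length}}$ (so rate × mean
length = 60 identically); `breathLengthCov()` uses the sample SD.
`timepointSnapshot()` picks, within ±1 min of an imaging time, the 5-s
sub-window with the least >10 Hz residual energy — the artefact criterion
is a free choice, since only "avoid artefacts" is prescribed — and
averages per-breath metrics there. `fiveBreathBlocks()` forms the
pre-event 5-breath block and six post-event blocks covering 30 breaths.

## Statistics

* `normalityGate()`: Shapiro-Wilk at α = 0.05 (the level is a choice; only
  the test is named in the plan), with rank tests forced for n < 3 or
  constant samples. The gate also selects the summary style (mean ± SEM vs
  median (IQR)).
* `timepointGroupTests()`: Mann-Whitney U per timepoint, Bonferroni
  adjusted across timepoints ($p_{adj} = \min(1, m\,p)$); mid-ranks and
  tie-corrected normal approximation for larger samples via R's
  `wilcox.test`.
* `repeatedMeasuresGroupModel()`: REML random-intercept-per-lamb model
  with categorical time and group fixed effects; Satterthwaite
  denominator degrees of freedom (lmerTest). Time is treated as
  categorical because the trajectory is strongly nonlinear in time and no
  functional form should be imposed at the testing stage. Singular fits
  (lamb variance at the boundary) warn rather than error: they are routine
  in null simulations and are not convergence failures. Under the null the
  group test rejects at ≈ 5 % (checked by simulation in the acceptance
  suite).
* `lambAdjustedRegression()`: fixed per-lamb intercepts with a common
  slope, one pooled $R^2$ per group — matching a per-group "within-lamb"
  regression; a per-lamb-slope variant is exposed as an option.
* `blocksVsBaseline()`: random-intercept model of the block metric with
  each post block compared to baseline under Dunnett familywise control.
  The Dunnett adjustment uses the established multivariate-t route
  (multcomp) rather than a bespoke Monte-Carlo max-|t|; Bonferroni is the
  fallback. Two blocks reduce to a paired comparison.
* `pairedMDD()`: exact inversion of the noncentral-t power function of a
  two-sided paired t-test (root-finding to $10^{-12}$). At small n this
  differs visibly from approximate formulas: with 17 pairs, difference SD
  0.1, 80 % power and α = 0.05 the exact MDD is 0.0724, whereas
  $z$-based or $\sqrt{n-1}$ shortcut formulas give 0.068–0.075 (0.075
  corresponds to ~83 % exact power). The package reports the exact value;
  a Monte-Carlo power check at the returned MDD is part of the acceptance
  suite.

## Problem sizes and numerical choices

The test and acceptance suites run the generator at the emulated cohort
size (10 + 9 lambs, 21 imaging timepoints, two lungs), with 60 reference
clips for calibration, 50 seeds for the group-effect power check, 600
null cohorts for the type-I check, 1000 toy timelines for the
backsliding oracle, 100 random ROIs for the CoV oracle, and 10,000
Monte-Carlo replicates for the power cross-check — sizes chosen so each
property is estimated with comfortable margin. Deterministic seeding makes
every run reproducible; the pipeline writes byte-identical CSVs for
identical seeds.

## Limitations

* The phantom is stylised: no scan conversion, attenuation, anatomy or
  drug effects; the rule-based grader reads cues the generator itself
  drew. Agreement statistics on synthetic clips say nothing about human
  inter-rater agreement on real images.
* Calibration is fitted on synthetic reference data; applying the package
  to real clips requires a calibration fitted against an independent
  aeration reference.
* DICOM multi-frame input is not supported (no DICOM reader is available
  to the package); clips are read and written as multi-page 8-bit TIFF.
* Generator noise parameters are plausible, not estimated; power and
  type-I results are statements about the emulated conditions.
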