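---
title: "Methods: scoring, criterion processing, concordance and calibration of the PAU-7S"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, criterion processing, concordance and calibration of the PAU-7S}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

The PAU-7S (Physical Activity Unit 7-item Screener) is a short
semi-quantitative questionnaire for measuring physical activity in
children and adolescents aged roughly 8–16. It asks, for the previous
week, on which days the child walked, played actively during recess,
played actively outside school, had physical education (PE), played a team
sport and played an individual sport, marking one time bin per day; two
qualitative items (aquatic activities, illness) are recorded but never
scored. This package implements the full measurement chain around the
instrument: scoring, accelerometer criterion processing, the
reliability/validity statistics battery, linear regression calibration
with cross-validated predictive validity, and a synthetic cohort
generator that makes every stage testable without access to real study
data.

## Questionnaire scoring

Each marked day contributes the minutes of its bin; weekly minutes are
divided by 7 to give minutes/day; MVPA (moderate-to-vigorous physical
activity) is the sum of all activities *except walking*, which is treated
as light intensity.

The instrument's bins are "less than 30 min", "30–60 min", "60–90 min"
and "more than 90 min". The minutes credited per bin are a scoring choice
of this package, not a property of the instrument: we use interval
midpoints **15/45/75** with midpoint extrapolation **105** for the open
top bin. Midpoints are the standard neutral choice for interval-censored
durations, and they reproduce the familiar per-day medians of population
cohorts exactly (e.g. the lowest bin on all five school days gives
`5 × 15 / 7 = 10.7` min/day of recess play). The map is configurable
through `pau_config(bin_minutes = ...)`.

The PE item has no time bins. We credit **30 minutes per marked PE day**
by default. A Spanish PE class nominally lasts 45 minutes, but cohort
tables report a PE median of 4.29 min/day `= 30/7`, i.e. one marked day
at 30 minutes — consistent with effective (rather than scheduled) active
time. Because the evidence is genuinely ambiguous we default to 30 and
expose `pe_minutes` in the configuration; no claim is made about the
instrument authors' intent.

Two further scoring rules: an unmarked or missing day counts as zero
minutes (the online instrument forces a selection, so absence means
"none", not "missing"), while a *whole item* absent from a response file
is a schema error; and responses flagged as "sick or prevented" are
scored normally and carried as a flag so downstream analyses can filter
them — exclusion is a study-design decision, not a scoring one. Recess
and PE accept marks Monday–Friday only; a non-zero weekend mark is
rejected naming the item and day.

## Accelerometer criterion

Wrist accelerometer epoch counts (vector magnitude, 5-s epochs by
default) are reduced to criterion MVPA in four stages:

1. **Non-wear**: a maximal run of zero counts lasting ≥ 60 min is
   non-wear. Runs are detected on the *full* series first and only then
   intersected with the daily wear window. The alternative — windowing
   first — would split a single overnight non-wear block at the window
   edge and could leave sub-threshold fragments counted as wear; treating
   wear-time identification inside the window as a separate, later step
   avoids that artefact. Strict zeros are required by default;
   `zero_run_tolerance` optionally permits short non-zero interruptions
   (the 1–2-min variant familiar from waist-worn protocols).
2. **Windowing**: wear minutes are accumulated over 08:00–22:00
   (left-closed, 840 min).
3. **Intensity**: worn epochs are classified by count cut-points,
   intervals closed on the lower bound. The shipped defaults are wrist
   vector-magnitude thresholds per 5-s epoch for children: sedentary
   ≤ 305, light 306–817, moderate 818–1968, vigorous ≥ 1969. They live in
   the configuration, not in code; users applying other devices, epoch
   lengths or placements must supply matching cut-points.
4. **Validity**: a day is valid with ≥ 600 worn minutes in the window
   (`>=` comparison, so 599 min fails and 600 passes); a participant is
   valid with ≥ 4 valid days of which ≥ 1 falls on a weekend. Means over
   valid days are unweighted — no weekday/weekend reweighting — because
   the measurement protocol itself balances the week. Participants with
   no valid days report missing summaries, never zero.

Raw `.gt3x` parsing, imputation of non-wear time and activity-type
recognition are out of scope; epoch CSV exports are the input format, and
an aggregation helper converts finer epochs to coarser ones.

## Concordance battery

All comparisons treat questionnaire MVPA as the *test* and accelerometer
MVPA as the *criterion*; differences are always test − criterion.

* **Cronbach's alpha** over the six item scores measures internal
  consistency.
* **ICC**: the package defaults to the two-way mixed-effects,
  consistency, single-measures coefficient, with the two-way random
  absolute-agreement variant selectable. The consistency default is the
  coefficient that coincides with the Pearson correlation when the two
  measurements share scale after calibration, which matches how the
  calibrated ICC is reported in validation studies of this design.
  Confidence intervals use the standard F constructions.
* **Correlation labels**: weak ≤ 0.20 < fair ≤ 0.40 < moderate ≤ 0.60 <
  good ≤ 0.80 < very good; the same boundaries label kappa as slight /
  fair / moderate / substantial / almost perfect.
* **Tercile concordance**: each method is split into empirical terciles
  of its own distribution (type-5, midpoint-interpolated quantiles, so
  membership depends only on order statistics and survives monotone
  transforms). Absolute agreement is the diagonal share,
  gross misclassification the opposite-corner share, and the weighted
  kappa uses linear weights by default (quadratic selectable) — linear
  weights are the conservative default when the original weighting is
  unreported. Ties heavy enough to prevent three non-empty groups raise
  an error listing the tied values.
* **Bland–Altman**: the classic variant reports the mean difference with
  a t-based CI and mean ± 1.96 SD limits of agreement; both variants
  regress the difference on the pairwise mean to estimate proportional
  bias; the Ludbrook variant models the bias as a function of that mean
  and replaces constant limits with ordinary-least-squares 95% t-based
  prediction bands around the fitted line.
* **Proportional agreement** is 100 × the mean per-participant ratio.
  The default direction is test/criterion, so an over-reporting
  questionnaire yields a value above 100%; the inverse direction remains
  selectable. (Published footnotes sometimes print the inverse formula
  next to values above 100% for an over-reporting test; the default here
  is the direction under which over-reporting exceeds 100%.)

## Calibration and predictive validity

Calibration regresses criterion MVPA on questionnaire MVPA with age, sex
and weight as covariables (ordinary least squares). Applying the fitted
model to its training rows yields calibrated values whose mean equals the
criterion mean *exactly* — the OLS-with-intercept identity that makes the
calibrated between-method difference zero. Variance inflation factors are
computed on every fit as a multicollinearity check and stored on the
model object.

Sex coding in such published equations is often unreported; the package
codes **boys = 1, girls = 0** by default, records the coding on the model
object, and makes it configurable. The rationale: boys report and log
more MVPA in this population, so a positive sex coefficient is concordant
under this coding. Negative calibrated predictions are returned as-is
with a warning — truncation would break the mean identity and is left to
the analyst.

Predictive validity uses leave-one-out cross-validation: each
participant's criterion value is predicted from the model fitted on the
other n − 1, and Pearson/Spearman/ICC are computed on the n held-out
pairs. The implementation uses the exact hat-matrix identity
`e_i / (1 − h_i)`, which equals the literal n-refit procedure to machine
precision (and is verified against it in the tests).

Construct validity fits sex- and age-adjusted regressions of zBMI or
waist-to-height ratio (WHtR) on MVPA, with the exposure scaled per
100 min/day so coefficients are readable. zBMI is accepted as an input
column; WHO growth-reference lookup is out of scope.

## The synthetic cohort generator

The generator is the package's test bed: it emulates a validation cohort
of Spanish 8–16-year-olds with two questionnaire administrations,
accelerometer criterion values and adiposity outcomes, with all
generative truths recorded.

* **Demographics**: age from a truncated normal on [8, 16] whose parent
  parameters are moment-matched so the *observed* mean/SD equal the
  targets (12.3 / 2.21 years); weight correlated 0.7 with age (a growth
  assumption — cohort tables are silent; it affects realism, not any
  recovery target); height linear in age; sex Bernoulli(149/321).
* **Items**: six latent weekly-minute scores from a one-factor
  equicorrelated model. A shared person factor carries the inter-item
  correlation; an administration-specific component sized by a retest
  parameter separates the two administrations; the person factor is
  negatively correlated with age (younger children report more
  activity), which is what transmits age structure into the marginal
  test–criterion correlation.
* **Discretisation**: latent weekly minutes are distributed greedily over
  the item's allowed days into the nearest bin (PE into 30-min days).
  This loses information — discretisation and flooring at zero shrink
  correlations and shift means — so the latent means/SDs and the three
  latent correlation parameters were tuned once, by a fixed-seed internal
  search at n = 20 000, until the *scored* cohort hits the observable
  targets: questionnaire MVPA mean 106.5 / SD 77.0 min/day, Cronbach
  alpha 0.76, test–retest ICC 0.71, marginal Spearman 0.31. The tuned
  constants are frozen in `sim_config()`; the per-item scored means
  behind them (walk 42, recess 15, free play 40, PE 4.3, team 27,
  individual 20.2 min/day) were chosen so the five non-walking items sum
  to the MVPA target with a composition consistent with the population
  medians.
* **Criterion**: accelerometer MVPA is the true linear calibration
  predictor — slopes −6.374 (age, years), +1.437 (sex, boys = 1), 0.080
  (questionnaire MVPA), −0.436 (weight, kg) — plus Gaussian noise whose
  SD is solved *per cohort* so the multiple correlation is 0.62. The
  model is parameterised mean-centred around a criterion mean of 95.2
  min/day rather than through a literal intercept: with these slopes and
  this population the implied intercept is ≈ 185, and anchoring the mean
  (a directly observable population moment) keeps every slope a
  recoverable truth while hitting the criterion's first moment. Residuals that would push a
  participant to or below zero MVPA are re-drawn (truncation by
  rejection, < 1% of draws): a child with valid wear never logs exactly
  zero, and ratio-based agreement statistics need a positive criterion.
* **Outcomes**: zBMI and WHtR are linear in questionnaire MVPA per
  100 min/day (true slopes −0.162 and −0.010) plus noise sized to the
  marginal SDs (1.25 and 0.06).

Reproducibility is a contract: the same seed and configuration give a
bit-identical cohort. `verify_moments()` recomputes every observable
target on a generated cohort and reports pass/fail at explicit
tolerances.

What the generator does *not* emulate: real item-response behaviour
(digit preferences, recall bias, differential misreporting by weight
status), seasonal variation, non-linear growth, missing data, or
accelerometer model error beyond Gaussian noise. Passing recovery tests
therefore demonstrates that the *pipeline* is correct and well
calibrated under the stated model — not that the instrument itself is
valid in any new population.

## Numerical choices and problem sizes

* Tercile boundaries: type-5 quantiles; boundary ties are resolved by
  the strict `>` comparison against interpolated boundaries; degenerate
  tie structures error rather than silently collapsing groups.
* Intensity intervals are closed on the lower bound; the day-validity
  and non-wear thresholds compare with `>=`.
* LOOCV uses the exact hat-matrix identity; leverages of 1 error out.
* Truncated-normal parent parameters are found by Nelder–Mead on the
  closed-form truncated moments (deterministic, no RNG).
* The test suite exercises parameter recovery at the validation-study
  size n = 304 over 100 generated cohorts (300 for CI-coverage checks,
  which are binomially noisier), and moment checks at n = 10 000; the
  acceptance script uses 100–500 cohorts per quantity. These sizes put
  Monte-Carlo error well below the assertion tolerances while keeping a
  full run in tens of seconds on one CPU.

## Known limitations

* Bin-minute values and the PE constant are conventions; analyses
  sensitive to them should vary `pau_config()` and report both.
* The wrist cut-point defaults are population- and device-specific.
* Proportional agreement's normal-approximation CI is crude for small n
  or near-zero criterion values.
* The agreement-model ICC CI uses the Satterthwaite approximation and
  can be slightly liberal for very small samples.
* The generator's equicorrelated one-factor item model is a deliberate
  simplification; it matches alpha by construction, not the full
  inter-item correlation matrix of real data.
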