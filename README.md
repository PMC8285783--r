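# pau7s

Scoring, validation and calibration of the **PAU-7S** (Physical Activity
Unit 7-item Screener), a short semi-quantitative questionnaire measuring
physical activity in children and adolescents (8–16 years).

Self-reported activity is cheap to collect but error-prone;
accelerometry is accurate but impractical at scale. A validation study
pairs both: the questionnaire is scored into minutes/day of
moderate-to-vigorous physical activity (MVPA), the accelerometer
provides the criterion, and a statistics battery quantifies reliability,
agreement and validity before and after regression calibration. This
package implements that entire chain for epidemiologists and instrument
developers:

* **Questionnaire scoring** — per-item, per-day time-bin marks → minutes
  per day of each activity, total PA and MVPA, where
  `MVPA = total PA − walking` and each marked day contributes the
  configured bin minutes (defaults: interval midpoints 15/45/75/105;
  PE days count a fixed 30 min).
* **Accelerometer reduction** — timestamped vector-magnitude epoch
  counts → non-wear detection (≥ 60-min zero runs), 08:00–22:00 wear
  accounting, cut-point intensity classification, valid-day
  (≥ 10 h worn) and valid-participant (≥ 4 days incl. ≥ 1 weekend day)
  rules → criterion MVPA min/day.
* **Concordance battery** — Cronbach α; ICC (two-way mixed consistency
  or two-way random agreement, single measures); Pearson/Spearman with
  qualitative labels; tercile cross-classification with linearly
  weighted κ; Bland–Altman (classic and Ludbrook prediction-band
  variants) with the proportional-bias regression of
  `d = test − criterion` on `(test + criterion)/2`; proportional
  agreement `100 × mean(test/criterion)`.
* **Calibration** — OLS of criterion MVPA on questionnaire MVPA + age +
  sex + weight:
  `MVPA_cal = b0 + b_age·age + b_sex·sex + b_q·MVPA_q + b_w·weight`,
  with VIF diagnostics, leave-one-out cross-validated predictive
  validity (exact hat-matrix identity), and sex/age-adjusted
  construct-validity regressions of zBMI and waist-to-height ratio on
  MVPA per 100 min/day.
* **Synthetic cohorts** — a generator whose defaults encode the
  validation-study population (age 12.3 ± 2.21 y, questionnaire MVPA
  106.5 ± 77.0, criterion 95.2 ± 33.2 min/day, α 0.76, retest ICC 0.71,
  marginal Spearman 0.31, calibration slopes as above), with recorded
  ground truth so every pipeline stage is testable.

## Worked example

Score one child's week, then run the validation battery on a synthetic
cohort:

```r
library(pau7s)
library(dplyr)

resp <- week_response("child-042", administration = 2, marks = list(
  WALK        = c(MON = 2, TUE = 2, WED = 1, THU = 2, FRI = 2),
  RECESS_PLAY = c(MON = 1, TUE = 1, WED = 1, THU = 1, FRI = 1),
  PE          = c(TUE = 1, THU = 1),
  TEAM_SPORT  = c(WED = 3, SAT = 4)
))
score_pau7s(resp) %>% select(walking:mvpa)
#>   walking recess_play free_play physical_education team_sport individual_sport
#> 1    27.9        10.7         0               8.57       25.7                0
#>   total_pa  mvpa
#> 1     72.9    45
```

Four walks of 30–60 min plus one short one are 195 weekly minutes →
27.9 min/day; five lowest-bin recess days give 75/7 = 10.7; two PE days
are 60/7 = 8.57; walking is excluded from MVPA, so MVPA is
72.9 − 27.9 = 45 min/day.

```r
sim <- simulate_cohort(n = 304, seed = 7)   # cohort + responses + truth
rep <- concordance_report(sim)
rep %>%
  filter(stratum == "all",
         statistic %in% c("between_method_difference", "spearman",
                          "icc", "weighted_kappa")) %>%
  select(method, statistic, estimate, lower, upper, label)
#>   method        statistic                  estimate  lower  upper label
#> 1 noncalibrated between_method_difference  1.13e+ 1  3.23  19.4   <NA>
#> 2 noncalibrated spearman                   2.50e- 1  0.142  0.353 fair
#> 3 noncalibrated icc                        2.20e- 1  0.110  0.324 <NA>
#> 4 noncalibrated weighted_kappa             1.45e- 1 NA     NA     slight
#> 5 calibrated    between_method_difference -2.36e-14 -2.83   2.83  <NA>
#> 6 calibrated    spearman                   5.65e- 1  0.483  0.637 moderate
#> 7 calibrated    icc                        5.24e- 1  0.438  0.601 <NA>
#> 8 calibrated    weighted_kappa             3.70e- 1 NA     NA     fair
```

The questionnaire over-reports MVPA by ~11 min/day and ranks children
only fairly; calibration removes the mean difference exactly (an OLS
identity) and lifts rank agreement substantially.

```r
fit <- fit_calibration(sim$cohort)
fit
#> <pau_calibration> n = 304
#>   calibrated MVPA = 177.508 + (-6.154 * age) + (2.012 * sex) + (0.082 * MVPA_q) + (-0.321 * weight)
#>   sex coding: boy = 1 | R^2 = 0.355 | residual SD = 25.20
#>   VIF: age=1.94 sex=1.01 mvpa_q=1.05 weight=1.91

glance(loocv_calibration(sim$cohort))
#>   pearson spearman   icc in_sample_pearson     n
#> 1   0.577    0.551 0.507             0.596   304
```

The refit recovers the generator's true slopes (age −6.374, sex +1.437,
MVPA 0.080, weight −0.436) within sampling error, and the held-out
correlation sits just below the in-sample one, as it should.
`autoplot(bland_altman(...))` and `plot_calibration()` draw the standard
agreement figures; `tidy()`/`glance()` return tibbles throughout.

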