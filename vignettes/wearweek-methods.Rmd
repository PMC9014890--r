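---
title: "Processing wearable step data for interrupted pre/post designs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing wearable step data for interrupted pre/post designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearweek)
```

## The problem

Consumer wrist-worn trackers (e.g. the Garmin Vivofit 4) record minute-level
step counts and a coarse motion-intensity signal, but they record them
whether or not the device is actually being worn, and only when the wearer
remembers to sync. Turning such exports into defensible physical-activity
outcomes for a natural experiment — here, a cohort of middle-school youths
observed across an abrupt school closure — requires a filtering chain before
any statistics: decide when the device was worn, decide which days are good
enough to count, aggregate days into weekly values that respect the
weekday/weekend structure of school life, decide which participants have
enough data on both sides of the interruption, and only then compare periods
with a model that respects repeated measures.

`wearweek` implements that chain end to end, plus a synthetic-cohort
generator with known ground truth, so every stage can be validated without
access to any raw device export.

## Processing rules

**Epochs.** Minute samples are binned onto a fixed clock-aligned 15-minute
grid (anchored at midnight, starts at :00/:15/:30/:45). Steps are summed and
motion intensity is maximised within each epoch. The grid alignment is a
convention choice: the rules below are insensitive to sub-epoch placement,
and clock alignment makes results reproducible across runs and tools.
Minutes absent from an export contribute nothing; wear status is decided
from intensity downstream, not at aggregation time.

**Nonwear.** An epoch is nonwear exactly when it belongs to a maximal run of
at least 3 consecutive epochs (45 minutes) whose maximum motion intensity is
zero. Runs are evaluated within each calendar day independently — a zero-run
spanning midnight is split at midnight before the length test — because the
day is the unit of all downstream rules and cross-midnight behaviour is
otherwise ill-defined. Any epoch with nonzero intensity is always wear. The
motion-intensity scale itself is treated as opaque: only zero versus nonzero
matters.

**Valid days.** A day is valid when it has (a) at least 480 minutes (8 h) of
wear whose epoch starts lie in the half-open window [09:00, 21:00) — exactly
48 epochs, so the full window is 720 minutes — and (b) at least 500 steps.
The step threshold is applied to total steps over worn epochs across the
whole day, not only inside the window: the two clauses are separate, and the
window qualifies only the wear-time clause. Steps in nonwear-flagged epochs
are excluded from totals; since nonwear epochs have zero intensity and the
device cannot register steps without intensity, this is a consistency choice
with no numeric effect (asserted by test). Days with no observed epochs are
omitted rather than reported as invalid, distinguishing "never synced" from
"worn but inactive".

**MVPA minutes.** The device-style rule counts a minute as
moderate-to-vigorous physical activity when the wearer runs for at least one
minute or walks for at least ten consecutive minutes. Cadence (steps per
minute) classifies minutes: run at or above 130, walk in [100, 130). Run
minutes always count; walk minutes count exactly when they lie inside a
maximal consecutive stretch of walk-or-run minutes of length at least 10, so
a brief run embedded in a long walk does not break the bout. Minutes absent
from the record are idle and do break continuity. The consumer device's true
classifier is proprietary; this is the plainest operationalisation of its
documented rule, and all four thresholds are exposed in `wear_config()` so
their sensitivity can be examined.

**Weekly aggregation.** Study weeks are consecutive Monday-anchored 7-day
blocks from a configured start date, so each week has exactly 5 weekdays and
2 weekend days. A week is valid when it contains at least one valid day. The
weekly value of an outcome is the weekday/weekend-weighted mean

$$\frac{5\,\bar{y}_{\text{weekday}} + 2\,\bar{y}_{\text{weekend}}}{7}$$

over valid days; when the week lacks a valid weekday or lacks a valid
weekend day, the fallback is the unweighted mean of all valid days. MVPA is
aggregated per day and reported per week as exactly 7 times the weighted
daily value, reconciling the daily scale of the validity rules with the
weekly scale on which MVPA outcomes are conventionally reported.

**Inclusion.** A participant enters the analysis only with at least one
valid week in the pre period (weeks 1–4 under the default design) and at
least one in the post period (weeks 5–8).

## The models

Two mixed-effects model families are fitted per outcome (steps/day and MVPA
min/week) on included participants' valid weeks, by REML:

$$y_{ij} = \beta_0 + \beta_1 \mathrm{post}_{ij} + \beta_2 \mathrm{wd}_{ij}
 + \beta_3 \mathrm{we}_{ij} + b_i + \varepsilon_{ij}, \qquad
 b_i \sim N(0, \sigma_u^2),\ \varepsilon_{ij} \sim N(0, \sigma^2)$$

where $\mathrm{wd}$ and $\mathrm{we}$ are the numbers of valid weekday and
weekend days in the week, and $b_i$ is a participant random intercept — the
minimal structure faithful to "weeks nested within participants", and the
richest a cohort of ~17 participants can support. The second family replaces
the period indicator with study week as a categorical fixed effect
(reference: the earliest week), yielding per-week trajectories. Estimated
marginal means are computed at the sample means of the covariates with 95%
CIs; F tests use Satterthwaite denominator degrees of freedom (recorded in
the result object). Missing weeks are handled by fitting the available data
(REML), with no imputation. Percent change is $100(\bar{y}_{post} -
\bar{y}_{pre})/\bar{y}_{pre}$, reported to one decimal with ties rounded
away from zero. Significance is two-sided at $\alpha = 0.05$. Demographic
composition of included versus excluded participants is compared with
Pearson chi-square tests without continuity correction; categories empty in
both groups are dropped first, since the test is undefined on structurally
zero margins.

Numerical edge cases: a fit whose optimizer fails raises a classed error; a
singular fit (a variance component estimated at zero, routine in small or
low-noise cohorts) raises a classed warning and returns the fit, because
zero variance components are legitimate REML solutions. When the
Satterthwaite machinery itself fails on near-degenerate data, the model is
refitted with plain `lme4` and asymptotic (z-based) intervals, and the
result records which method was used; a fully constant outcome short-circuits
to the exact degenerate answer (all effects zero, means equal to the
constant) with a diagnostic warning, since the REML problem has no variance
left to estimate.

## The synthetic cohort

`generate_cohort()` emulates the structure of the motivating study rather
than any individual's behaviour. Defaults are the study conditions: 17
participants, 8 weeks, closure at week 5, weighted pre-closure means of 8003
steps/day and 80.18/7 ≈ 11.45 MVPA min/day, post/pre ratios 0.546 (steps)
and 0.575 (MVPA), wear-day probability 0.75 (targeting the reported ~5.2
valid days per week), and a 15% per-participant probability of losing all
post-closure data, mirroring the switch from supervised in-school syncing to
unsupervised home syncing.

Participant heterogeneity is lognormal with unit mean (SD 1500 steps/day,
3 MVPA min/day, as coefficients of variation on the configured means),
reflecting the positive skew of activity distributions; day-level noise is
normal censored at zero (SD 1800 steps, 3 MVPA min), with the location
parameter solved numerically so the censored draw's expectation equals the
target mean exactly — naive zero-clipping would otherwise inflate low
post-closure MVPA means by a few tenths of a percent and bias effect-ratio
recovery. Weekend days run at
0.9 times weekday levels — enough contrast to exercise the 5/7–2/7
weighting, while the weekday-level means are solved internally so the
weighted weekly expectation stays exactly on target. Each wear day is
realised as a wear block (~07:00–08:30 to ~21:30–23:00) with up to two
random 20–70-minute gaps; the day's MVPA target is placed as one consecutive
walk bout (cadence 102–128) plus scattered run minutes (cadence 132–160,
roughly 20% of MVPA), the residual step target as scattered sub-threshold
"light" minutes (cadence 30–95), and remaining worn minutes as zero-step,
intensity-1 idle minutes. Non-wear days are simply absent from the file.
This construction makes the pipeline's recovered quantities equal the
generated targets by design, which is what makes end-to-end parameter
recovery a sharp test.

What the generator does **not** emulate: circadian microstructure, weather
and seasonality, school timetables beyond the weekday/weekend contrast,
partial-day syncing artefacts, or any device firmware quirks beyond the
stated rules. Passing tests therefore demonstrate that the pipeline
implements its rules correctly and that the models recover known effects
under realistic noise and missingness — not that any particular real cohort
satisfies the generator's assumptions.

`simulate_week_summaries()` draws the same truth structure directly at the
week level (skipping minute synthesis). It exists for statistical
calibration studies that need hundreds of simulated cohorts — type-I error
and effect-recovery checks use it at 40 participants × 200–500 replicates,
sizes chosen to keep Monte-Carlo error small while the whole suite stays
fast — whereas the minute-level path is exercised end to end in the
pipeline tests and a 50-replicate recovery check.

## Design choices that were genuinely open

- **Week boundaries.** Study weeks are Monday-anchored blocks from a
  configured start date; the closure boundary is explicit in
  `study_design()` rather than inferred from a calendar, because the
  mapping from calendar events to study weeks is a property of the study,
  not of the data.
- **MVPA per week = 7 × weighted MVPA per day.** Validity and weighting are
  daily-scale rules while MVPA outcomes are reported weekly; the ×7
  convention reconciles the two scales exactly and is applied uniformly.
- **Timezones.** All timestamps are wall-clock local time (handled as UTC
  internally), so the 9 AM–9 PM window and day boundaries are unaffected by
  daylight-saving transitions; days are wall-clock days throughout.
- **Estimated means.** Covariates are held at their sample means (the
  standard estimated-marginal-means convention); the results bundle reports
  model-based standard errors and labels them as such.
- **Rounding.** Weekly values are carried at full floating precision;
  rounding happens only at reporting (steps to integer display, percent
  change to one decimal, half away from zero).

## Limitations

Denominator degrees of freedom from small mixed models are
approximation-dependent; the package records the method (Satterthwaite)
rather than matching any particular software's bookkeeping. The
motion-intensity scale is opaque, so nonwear detection cannot be made more
graded than zero/nonzero. The MVPA rule is an operationalisation of a
proprietary classifier and should not be read as replicating the device
firmware. And because the generator's variance parameters are modelling
choices constrained only by reported means and standard errors, synthetic
standard errors are comparable in magnitude to, but not calibrated against,
any real cohort.

## A worked run

```{r, eval = FALSE}
src <- tempfile(); out <- tempfile()
generate_cohort(synthetic_config(seed = 1), out_dir = src)
res <- run_pipeline(src, out)
res$results$results_table
plot(res$weekly_models$steps_per_day)
```
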