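---
title: "Scoring infant looking and modelling in-home air-quality exposure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring infant looking and modelling in-home air-quality exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazecog)
```

## The problem

In a preferential-looking change-detection task, an infant watches two
side-by-side arrays of coloured squares blink on (500 ms) and off (250 ms)
for 10 s. One array is static; in the other, one square changes colour after
every blink. An infant who holds the array in visual working memory loses
interest in the static side and looks toward the changing one. Looking is
recorded either by a corneal-reflection eye tracker at 500 Hz or, when no
track is available, hand-coded from video at 30 frames per second; both
arrive as a per-trial time series over the labels *left*, *right*, *away*,
*missing*.

The same families carry an in-home particulate (PM2.5) monitor logging a US
AQI reading every 10 s for three-day rounds, up to six rounds across two
years. The scientific question is whether household air quality is
associated with the looking-based cognition measures once family
socio-economic status (SES) and age cohort are controlled.

`gazecog` implements the full chain — gaze scoring, exposure modelling,
mixed-effects association — plus a seeded synthetic-data generator with a
ground-truth ledger so that every stage can be validated by parameter
recovery rather than against an external dataset.

## Looking measures

All measures are computed on *time-weighted AOI intervals*: each sample's
label holds over the half-open interval to the next sample, so 500 Hz and
30 fps streams are commensurable without resampling and without aliasing
decisions.

* **First-look class.** A trial is sorted by the AOI occupied at the onset
  of the first colour change (1000 ms). If that sample is away or missing —
  neither answers *where on the displays* the infant was looking — the
  class is taken from the first left/right sample up to 2500 ms (two
  on/off display cycles past the onset); failing that the trial is
  unclassified. The fallback bound is inclusive: a display sample at
  exactly 2500 ms classifies, one at 2501 ms does not.
* **Change preference (CP).** Within the 1750–6750 ms analysis window, time
  on the changing display divided by time on either display. Away and
  missing time is excluded from the denominator: CP is a preference between
  the two arrays, not a measure of attentiveness. Trials whose off-screen
  fraction (away plus missing, over the whole trial) strictly exceeds 0.75
  are excluded; exactly 0.75 is retained — we read "more than 75%"
  literally and pin the boundary with a test. A window-restricted
  off-screen fraction is available as a configuration switch.
* **Shift rate.** Over the full trial, the stream is collapsed to its
  sequence of on-screen looks; gaps of away/missing neither break a switch
  nor count as looking time. The rate is switches between sides divided by
  seconds of on-display looking — a visual processing-speed measure.
* **LookingWindow1.** In the 1–750 ms window, before any change exists, the
  share of on-display looking spent on the first-fixated side; a
  per-infant covariate for baseline visual dynamics.
* **Coder reliability.** Cohen's kappa on frame-aligned label sequences,
  with the degenerate both-coders-constant case reported as a
  perfect-agreement special case rather than a kappa.

Trial timing constants all live in `task_config()` and are configurable;
the defaults are the task's published values. One arithmetic oddity is left
as-is: with a 500/250 ms cycle starting at 0, display onsets fall at 750 ms
multiples, yet the first change is anchored at 1000 ms. We treat the onset
as a free constant defaulting to 1000 ms and do not attempt to reconcile
the cycle arithmetic.

Every measure has an independent per-millisecond brute-force oracle in the
test suite; the interval implementation must agree with it exactly on
integer-millisecond streams, and a mirror-symmetry property (relabelling
left and right changes nothing) is enforced on randomized trials.

## Exposure model

Device logs are first filtered: readings outside plausibility bounds
(default 1–500 AQI) are flagged, and a device whose flagged fraction in a
round exceeds 10% is retired from that round onward (forward-only — the
study narrative does not say whether retirement was retroactive, and we
keep past rounds). Household-rounds with under 5 h of recorded coverage are
dropped, the boundary inclusive; coverage is defined as sample count times
the nominal 10 s cadence, which makes the boundary exact and testable.
Retained readings are down-sampled to hourly means (no imputation of empty
hours).

Hourly AQI is then modelled with a generalized additive mixed model fit by
`mgcv::bam`: a tensor-product smooth of clock hour and calendar date with
cubic regression splines of 11 basis dimensions per margin, and a shrunken
per-household intercept (`s(household, bs = "re")`). The hour margin uses a
*cyclic* spline — 23:00 adjoins 00:00; diurnal continuity demands it even
though nothing in the design forces the choice. Residual autocorrelation is
handled with a fixed AR(1) coefficient of 0.6 applied within chains of
consecutive hours; a gap of more than one hour, or a new household-round,
starts a new chain.

The *exposure score* for a household is its shrunken intercept, centered so
the sample mean is zero: positive means poorer air than the grand mean. The
grand mean is reported alongside so the scores can be placed back on the
AQI scale. Shrinkage matters when a household contributed few hours, where
a raw mean is biased by time of day and season; on synthetic data the
scores nonetheless correlate strongly with naive household means, and
recovery of known offsets (SD 30 AQI, four rounds per household) exceeds
r = 0.9 by a wide margin.

Conversions between PM2.5 concentration and AQI use the EPA piecewise-linear
breakpoint table (pre-2024 PM2.5 sub-index), with the standard category
bands (good ≤ 50, moderate 51–100, unhealthy-for-sensitive-groups 101–150,
unhealthy 151–200, very unhealthy 201–300, hazardous above that).

## Association models

The analysis unit is the participant × year × load-level cell mean
(separately per first-look class for CP), keeping the random structure at a
participant intercept; trial-level analysis is possible by passing the trial
table instead. Coding follows the reporting convention: two-level year and
age cohort difference-coded to ±0.5, SES centered, load as a three-level
factor with sum-to-zero contrasts whose columns print as `Load1`/`Load2`.
Load level is the *within-year rank* of the absolute load — year 1 uses
1/2/3 items, year 2 uses 2/4/6, so absolute load 2 is "medium" in year 1
and "low" in year 2.

`build_baseline()` starts from main effects and forward-selects candidate
interactions (two-way before three-way before four-way, marginality
respected) by maximum-likelihood likelihood-ratio tests at α = 0.05; the
selected model is refit by REML for reporting — the conventional split for
fixed-effect selection in mixed models. `add_air_quality()` adds the
centered exposure score in raw AQI units (hence per-unit coefficients of
order 10⁻³ on the looking measures) and tests a Year × AQI interaction the
same way. Reported tables carry Satterthwaite degrees of freedom and
p-values (via `lmerTest`), per-term type-3 Wald χ² computed as the
quadratic form over the term's coefficient covariance block, and partial
η² = χ²/(χ² + df_error) with the term's Satterthwaite error df — the
convention under which a χ²(1) of ~4.7 with ~190 error df yields η²ₚ ≈
0.02. Robustness refits (each looking measure as a covariate in the other's
model; the load-matched absolute-load-2 subset) are one call each.

Assessment scores (a year-1 cognitive composite, year-2 questionnaire
scores) are plain linear models on age cohort and SES, with and without the
exposure score — there is one score per participant-year, so no random
structure.

## The synthetic generator

`gen_config()` defaults encode the emulated design: 215 households, rounds
of 3 days at 10 s cadence (up to 6; default 4, the average completed), 36
trials in 6 blocks balanced over three loads and two change sides,
eye-tracking at 500 Hz with 30% of trials video-coded at 30 fps, 10%
missing samples.

The AQI series is seasonal cosine (amplitude 60, peaking mid-January) plus
Gaussian meal-time bumps at 07:00 and 18:00 (amplitude 40, SD 1.5 h) plus a
household offset and AR(1) noise, floored at zero and anchored at a
baseline of 186 AQI. Household offsets are a cooking-fuel effect (cow dung
> wood > LPG), an SES slope of −1.15 AQI per SES unit, and household noise
(SD 20) — realized offsets have SD ≈ 28 AQI. Fuel assignment probabilities
are conditioned on the SES screening group so LPG concentrates in high-SES
homes.

Gaze streams come from a two-state semi-Markov look process: exponential
look durations, occasional away gaps, and a per-trial "detection" draw
whose probability rises with (capacity − load). Detection biases both
dwells and release directions toward the changing display — that is what
produces above-chance CP for no-change starters and the load gradient.
Capacity per cohort/year and its exposure slope, and the switch intensity
and its exposure slope, come from the truth ledger. The look intensity is
renormalized between the detect/non-detect regimes so the realized switch
rate tracks the ledger's shift-rate model in both; without this, capacity
effects leak into shift rate and the generator's two exposure channels are
not separable. Look-duration distributions are a modelling choice — the
study reports none — so recovery tests make claims about the scoring and
models, not about real gaze kinematics.

Effect-size defaults are the reported coefficient magnitudes: −0.001
shifts/s per AQI unit on processing speed, and a −0.001 CP/AQI effect in
year 1 attenuated to zero in year 2 (the reported pattern). A design note
worth recording: with the study's noise structure at 200 participants,
an effect tuned to an *observed* partial η² of 0.02 would have ~55% power,
so the generator pins the printed per-unit coefficient instead, giving
~85–95% power for the shift-rate test and observed η²ₚ of roughly
0.04–0.08. Assessment scores carry a positive SES effect (0.8 points per
SES unit) and an exactly null exposure effect — the generator's null for
the specificity analyses.

`simulate_score_table()` is a scaled generator that draws analysis-cell
means directly from the ledger's linear model, for power and type-I-error
simulations where regenerating streams hundreds of times would add nothing;
the stream-level and cell-level generators share the same ledger
parameters.

All generators are deterministic given (config, seed), and every simulated
dataset ships with its `truth.json` ledger; recovery tests read truth only
from the ledger.

## What the synthetic data does not emulate

Calibration drift within a device round, infant fussiness and block breaks,
gaze-position noise at AOI boundaries (streams are generated directly in
AOI space), correlated missingness (dropouts are i.i.d.), outdoor-station
comparison series, and any demographic realism beyond the qualitative
fuel × SES × electricity structure. Passing recovery tests therefore
demonstrates correctness of the scoring and modelling machinery under the
stated generative assumptions, not robustness to every failure mode of
field data.

## Numerical choices and problem sizes

Tolerances: exposure-score centering and translation-equivariance to 1e-6;
oracle agreement exact (1e-12) on integer-millisecond streams; Wald
quadratic forms against an independent matrix oracle to 1e-10. Degenerate
inputs are values, not errors, wherever the field convention says so
(unclassified first looks, undefined CP/shift rate); genuinely impossible
fits (one household, too few distinct dates for the basis) fail with
guidance.

Test and acceptance runs use scaled sizes chosen to make each check
statistically decisive: 100–250 households for exposure recovery (device
cadence thinned to 5-minute samples, which leaves the hourly means
essentially unchanged), 200 participants and 200–500 cell-level replicates
for power and type-I error, and 500+ randomized trials for the scoring
oracle. The vignette's sizes are the package's own choices for decisive yet
fast checks; the generator's defaults remain the full study design.

## Worked example

```{r example, eval = FALSE}
hh <- generate_households(60, seed = 1)
truth <- make_truth(hh, seed = 2)
cfg <- gen_config(n_households = 60, n_rounds = 4, sample_interval_s = 300,
                  trial_count = 12, blocks = 2, sample_rate_hz = 50)

logs <- generate_aqi_logs(hh, cfg, truth, seed = 3)
hourly <- downsample_hourly(qc_rounds(logs, sample_interval_s = 300)$records)
exposure <- extract_exposure(fit_exposure_model(hourly))

trials <- generate_gaze_trials(hh, truth, cfg, seed = 4)
scored <- score_dataset(trials)
tabs <- build_analysis_tables(scored, hh, exposure)

coded <- code_predictors(tabs$shift)$data
base <- build_baseline(coded, "shift",
                       main_effects = c("Year", "Load", "SES", "Age"))
aug <- add_air_quality(base, coded)
coef_table(aug)
wald_type3(aug)
```

Or, end to end with one call writing all artifacts:

```{r pipeline, eval = FALSE}
run_pipeline(list(simulate = list(n_households = 60, n_rounds = 2,
                                  sample_interval_s = 600,
                                  trial_count = 12, blocks = 2,
                                  sample_rate_hz = 50),
                  exposure = list(sample_interval_s = 600),
                  seed = 1),
             out_dir = "run1")
```
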