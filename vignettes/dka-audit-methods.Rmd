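---
title: "Methods: guideline-adherence auditing for DKA care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: guideline-adherence auditing for DKA care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dkaudit)
```

`dkaudit` turns raw DKA episode records — timestamped labs, insulin and
fluid prescriptions, discharge coding — into per-episode guideline-adherence
scores, complication flags, quarterly per-hospital key performance
indicators, and anonymised feedback reports. This vignette is the package's
account of the underlying definitions, the conventions it had to fix where
the clinical guideline leaves room, and what the synthetic-cohort generator
does and does not establish.

## Data model

Four flat tables describe a cohort (`read_cohort()` / `write_cohort()`):

- `episodes.csv` — `episode_code` (opaque pseudonym), `hospital_code`,
  `age_years` (≥ 16; adult guideline), `sex`, `diabetes_type`
  (`t1dm`/`t2dm`/`unknown`), `has_diabetes_history`, `weight_kg`,
  `admission`, `discharge` (ISO `YYYY-MM-DDTHH:MM`), plus optional
  `urine_ketones` (≥ ++ on admission) and `confirmed` (manual adjudication
  override).
- `observations.csv` — `episode_code`, `timestamp`, `analyte`
  (`glucose`, `ketones`, `ph`, `bicarbonate`, `potassium`, `sbp`), `value`
  (mmol/L except pH, dimensionless in [6.5, 8.0], and systolic BP in mmHg).
- `prescriptions.csv` — `kind` `frii` (with `rate_units_per_h`) or `fluid`
  (with `volume_ml`), `start`.
- `discharge_codes.csv` — ICD-10 `icd10` per episode.

Timestamps are timezone-naive local times at minute resolution (a
single-country registry has no timezone ambiguity worth modelling).
Validation is total: every malformed row fails with a classed condition
naming the file, row and field; nothing is silently coerced. Observations
are stably sorted by time within an episode, so charting ties keep file
order.

## Case ascertainment

Screening (`screen_candidates()`) unions episodes coded with a DKA ICD-10
code (E10–E14, fourth digit 0 or 1) and episodes treated with a fixed-rate
insulin infusion; the second arm recovers admissions the coding missed. The
subsequent deterministic adjudication is `detect_diagnosis()`; a `confirmed`
column reproduces a human adjudication where one exists (`FALSE` forces an
episode out, `TRUE` keeps it whenever a diagnosis time exists).

Diagnosis at time *t* (`meets_dka_criteria()`):
(glucose > 11 mmol/L OR documented diabetes) AND (blood ketones > 3 mmol/L
OR urine ketones ≥ ++) AND (pH < 7.30 OR bicarbonate < 15 mmol/L), each arm
evaluated on the most recent reading of its analyte at or before *t*.
Two conventions are ours, because the guideline is silent:

- **Staleness lookback, 6 h** (`lookback_h`): a reading older than 6 hours
  no longer represents "the most recent" state — without a bound, a day-old
  admission glucose could validate a diagnosis against fresh acid-base
  results. Six hours is comfortably longer than any monitoring interval the
  guideline contemplates and shorter than an admission day.
- **Indeterminacy is not falsity**: with no ketone or no acid-base datum in
  the lookback, the criteria return `NA`, distinct from `FALSE` — an episode
  that cannot be assessed is not thereby a non-case. A missing glucose with
  no diabetes history fails that arm determinately (history is a datum).

The diagnosis time is the earliest observation timestamp at which the
criteria hold. Resolution (`detect_resolution()`) is "pH > 7.30 or
bicarbonate > 18 mmol/L and blood ketones < 0.6 mmol/L for two consecutive
hours". Real monitoring is not exactly hourly, and the sustained-interval
reading of "two consecutive hours" is not assessable from discrete charts,
so the package reads it as **two reading times 60 ± 15 min apart** at both
of which the composite condition holds (`res_gap_min`, `res_gap_tol_min`).
The earliest qualifying pair wins and resolution is stamped at its **second**
reading — the criterion is not established until sustained — configurable to
the first (`res_mark`). Resolution always requires blood ketones; the urine
surrogate applies to diagnosis only, since the resolution threshold
(0.6 mmol/L) has no urine equivalent. DKA duration is
diagnosis-to-resolution in fractional hours; both detectors are invariant
under uniform time translation, which the tests assert.

## Adherence scoring

Four indicators per episode (`score_adherence()`), each a percentage of the
guideline recommendation, banded by the inclusive ±20% window
(`band_low = 80`, `band_high = 120`; "80%–120%" conventionally includes its
endpoints). Banding is computed at full precision; the one-decimal rounding
applied in emitted CSVs can disagree only within 0.05 of a bound, where full
precision decides.

- **FRIII**: `(rate / (weight/10)) × 100`, i.e. percent of 0.1 units/kg/h.
  Scored on the *first* FRIII prescription by start time — the initial
  prescribing decision is the audited act. The 2021 two-rate revision
  (0.05 units/kg/h below glucose 14 mmol/L) is deliberately not folded in:
  the audited formula has a single rate, and scoring a rate reduction as
  half-adherence would misread guideline-compliant care; the rate constant
  is configurable (`frii_rate_per_kg`).
- **Fluids**: administered ÷ recommended × 100, where administered sums
  fluid volumes starting inside the closed DKA window. The recommended
  schedule (`fluid_schedule()`) reconstructs the guideline prose — boluses
  totalling 1000 mL, then 1 L bags over 1, 2, 2, 4, 4, 6 h, then 1 L per
  6 h until resolution — with **whole-bag accrual**: a bag's volume is
  credited when its interval completes. This is the unique natural
  calibration reproducing the anchor of 4 L recommended for a 5 h episode
  (1 L bolus + bags completing at 1, 3 and 5 h); pro-rata accrual cannot
  produce an integer 4 L there (it gives the same value only at bag
  boundaries). Both the schedule and the accrual mode (`pro_rata`) are
  configurable so an alternative formula table can be dropped in.
- **Glucose / ketone monitoring**: `(readings / duration_h) × 100`, counting
  distinct reading times in the closed window `[diagnosis, resolution]` —
  the closed interval matches the worked anchor of 5 readings ↔ 100% for a
  5 h episode; duplicate charting at one minute counts once. Scores above
  100% (over-monitoring) are not truncated; the 120% band edge already
  handles them. A zero-hour duration leaves monitoring undefined (`NA`).

Unresolved episodes get only the FRIII score: the other three need a
duration. Missing weight or a missing FRIII prescription leaves the FRIII
score absent (the former with a warning).

## Complications, outcomes, aggregation

Complications are flagged **per episode** over the DKA window (diagnosis to
resolution, or discharge when unresolved): hypoglycaemia is any glucose
strictly below 4 mmol/L; potassium below 3.5 / above 5.5 mmol/L flags hypo-
and hyperkalaemia, which can both be true at different times. Episode-level
counting keeps proportions in [0, 1] with episode denominators. An empty
denominator yields `NA`, never 0.

Quarters are calendar quarters of the **admission** date (the admission
defines the care episode). Medians and IQRs use SPSS-style weighted-average
quantiles (`stats::quantile` type 6, configurable): on durations
{4, 6, 8, 10, 12} this gives median 8, IQR (5, 11). Unresolved episodes
stay in complication denominators and length-of-stay summaries but not in
duration medians. The first-vs-last-quarter comparison is an uncorrected
Pearson chi-square on the 2×2 in-band × quarter table, 1 df (Yates
correction is a switch, off by default to match raw reporting); results with
any expected cell below 1 are flagged unreliable rather than suppressed. A
hospital's "first quarter" is its earliest quarter containing data, which
accommodates staggered onboarding without a hand-maintained calendar. No
multiplicity adjustment is applied by default (`first_last_comparisons()`
offers `p_adjust`). Feedback reports are deterministic markdown — trend
tables for the trailing four quarters against the pooled anonymised peer
series — so report rendering is byte-identical on identical inputs and
carries no plotting dependency.

## The synthetic cohort generator

`generate_cohort(sim_config(...))` emulates a multi-hospital DKA registry
well enough to exercise and validate every pipeline stage, with a
ground-truth table of what was generated. Defaults describe a three-year,
eleven-hospital audit: onboarding staggered 3 + 2 + 6 hospitals over
2020–2022 with per-quarter Poisson intensities summing to roughly 2,000
episodes; ages lognormal with median 45 (IQR 29–61) years truncated at 16;
1.29 men per woman; weights lognormal (mean 80, SD 18 kg); DKA duration
lognormal with median 15 h (IQR 9–26) via quantile matching, bracketing the
range of quarterly medians a multi-centre audit observes; length of stay
median 3.3 d (IQR 1.7–6.3); in-band probabilities (FRIII 0.85, fluids 0.35,
glucose 0.35, ketones 0.50) and complication rates (hypoglycaemia 0.08,
hypokalaemia 0.25, hyperkalaemia 0.10) in the ranges multi-centre DKA
audits report. These were fixed once as the simulated study conditions.

The construction is anchor-based, not physiological: each episode admits in
DKA (glucose 25, ketones 5.8, pH 7.05, bicarbonate 10 at admission), holds
ketones ≥ 0.9 and acidotic chemistry until hour *H*−2, and normalises at
hours *H*−1 and *H*, where *H* is the sampled integer duration (clamped to
[5, 120] h). Readings sit on an hourly grid with shared per-anchor jitter of
at most ±7 min:

- the qualifying pair at *H*−1 and *H* is then 60 ± 14 min apart, always
  inside the 60 ± 15 detection tolerance, so resolution lands exactly on the
  anchor-*H* timestamp and the truth table records the realised duration;
- adherence factors are 1.0 for in-band draws, otherwise pushed at least
  0.22 beyond 1.0, so FRIII and fluid percentages (rate = 0.1 × weight ×
  factor; volume = recommended(realised duration) × factor) carry their band
  label exactly;
- monitoring counts are chosen as *n = H* (in band) or decisively outside
  (*n* ≤ ⌈0.8 H⌉ − 1 or *n* ≥ ⌊1.2 H⌋ + 1). Because 0.8 H and 1.2 H land on
  multiples of 0.2 for integer H, the margin to the band edge is at least
  0.2 readings, while ±7 min of jitter shifts the realised ratio by at most
  0.14 — labels survive jitter. This margin calculus is why the generator
  insists on durations ≥ 5 h and jitter ≤ 7 min (`sim_config()` rejects
  anything else as infeasible).

Complication excursions (glucose 3.2; potassium 3.0 / 5.9) are injected at
interior anchors per the configured rates, so detection is guaranteed, and a
configurable fraction of episodes is miscoded to a non-DKA discharge code to
exercise the FRIII-screening arm. Identical seed and configuration give
identical cohorts; the caller's RNG state is restored afterwards.

What this does and does not show: passing recovery tests demonstrate that
the pipeline computes the definitions correctly and without bias on data
whose truth is known — they say nothing about charting noise, missing
analytes, transcription error, relapsing-remitting biochemistry or coding
idiosyncrasies in real registries, which the generator deliberately does not
model. `truth_compare()` quantifies recovery; on generated cohorts it is
exact (zero label mismatches, zero duration discrepancy).

## Test design and problem sizes

The suite validates the detectors against independent brute-force oracles
(exhaustive timestamp and pair scans) on 1,000 randomised episodes with
threshold settings varied across runs, the Pearson statistic against its
closed form on 1,000 random 2×2 tables (tolerance 1e-9) and against
`chisq.test()`, and parameter recovery on a 500-episode cohort. The recovery
check makes 7 simultaneous binomial comparisons (four in-band proportions,
three complication rates) under one fixed seed; it uses the Bonferroni
family-wise 95% interval, `z = qnorm(1 − 0.025/7)`, rather than
per-comparison 95% intervals, whose ~30% family false-alarm rate would make
a single-seed check uninformative. Round-trip, conservation (pooled counts
equal per-hospital sums) and translation-invariance properties run on
smaller randomised cohorts; these sizes keep the full suite around a minute
on one CPU while leaving every property with real statistical content.

## Known limitations

- The "two consecutive hours" resolution rule is read as two qualifying
  readings about an hour apart; a continuously-satisfied-interval reading
  would need denser data than quarterly audits collect.
- The fluid schedule is a prose reconstruction calibrated to the 4 L / 5 h
  anchor; hospitals using a different formula table should override
  `fluid_schedule()`.
- Potassium-replacement content of fluid bags and long-acting insulin
  continuation are not scored; no metric is defined for them.
- No process-control charting or interrupted time-series estimation: the
  package measures adherence and outcomes, it does not attribute changes to
  interventions.
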