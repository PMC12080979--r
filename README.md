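# dkaudit

Audit-and-feedback analytics for diabetic ketoacidosis (DKA) care in adults.

Hospital teams running a DKA quality-improvement cycle face the same pipeline
every quarter: pull candidate admissions from discharge coding, confirm which
ones really were DKA, work out how closely each episode's management followed
the national (JBDS-IP) guideline, count treatment complications, and feed the
trends back to clinicians alongside an anonymised peer comparison. `dkaudit`
implements that pipeline as tested, reusable R functions over flat CSV
registry extracts, plus a seeded synthetic-cohort generator so the whole
pipeline can be exercised and validated without access to any clinical data.

## What it computes

**Case ascertainment.** Candidate episodes are the union of admissions coded
E10–E14 with fourth digit 0/1 (diabetes with coma/ketoacidosis) and
admissions treated with a fixed-rate intravenous insulin infusion (FRIII).
Diagnosis at time *t* requires, using the most recent reading of each analyte
(6 h staleness window):

    (glucose > 11 mmol/L  OR  known diabetes)
    AND (blood ketones > 3 mmol/L  OR  urine ketones ≥ ++)
    AND (pH < 7.30  OR  bicarbonate < 15 mmol/L)

Resolution requires (pH > 7.30 OR bicarbonate > 18 mmol/L) AND blood ketones
< 0.6 mmol/L sustained over two consecutive readings 60 ± 15 min apart; DKA
duration is diagnosis-to-resolution in hours.

**Adherence scoring**, per episode, as a percentage of the guideline
recommendation, with the ±20% window (80–120%, inclusive) classifying an
episode as "in band":

- FRIII: `(rate / (weight/10)) × 100` — 0.1 units/kg/h is 100%.
- Fluids: administered volume ÷ recommended volume at the episode's
  duration. The recommended schedule is a 1 L bolus then 1 L bags over
  1, 2, 2, 4, 4 and 6 h (then 1 L per 6 h until resolution), credited at bag
  completion: 4 L for a 5 h episode.
- Glucose and ketone monitoring: `(readings / duration in hours) × 100`
  (hourly monitoring is 100%).

**Complications and outcomes.** Hypoglycaemia (glucose < 4 mmol/L),
hypokalaemia (K⁺ < 3.5) and hyperkalaemia (K⁺ > 5.5) during the DKA window,
flagged per episode; DKA duration and length of stay summarised as median
(IQR), SPSS-style type-6 quantiles.

**Quarterly feedback.** Per-hospital calendar-quarter KPIs (in-band
proportions, complication proportions, outcome medians), first-vs-last
quarter Pearson chi-square (2×2, uncorrected, 1 df:
`n(ad−bc)²/((a+b)(c+d)(a+c)(b+d))`), and deterministic markdown feedback
reports against the pooled anonymised peer series.

## Worked example

```r
library(dkaudit)

frii_adherence(c(7, 3.5, 14), 70)
#> [1] 100  50 200

sim <- generate_cohort(sim_config(
  seed = 2024,
  hospitals = data.frame(code = c("A", "B"), onboard_quarter = "2022-Q1",
                         episodes_per_quarter = 20, poisson = FALSE),
  end_quarter = "2022-Q4"))

scores <- dka_pipeline(sim$cohort)
scores
#> <dka_scores>
#>   160 candidate episodes; 160 diagnosed, 160 resolved
#>   frii    in band: 134/160
#>   fluid   in band: 56/160
#>   glucose in band: 60/160
#>   ketone  in band: 76/160

kpis <- aggregate_kpis(sim$cohort, scores, pooled = TRUE)
first_last_comparison(kpis, "A", "fluid")
#> # A tibble: 1 × 9
#>   hospital_code indicator first_quarter last_quarter first_prop last_prop ...
#> 1 A             fluid     2022-Q1       2022-Q4             0.5      0.35
```

Every generated episode is diagnosed and resolved by the detectors, and the
ground-truth table is recovered exactly — `truth_compare(sim, scores)`
reports zero label mismatches and zero duration discrepancy, with recovered
in-band proportions (0.838, 0.35, 0.375, 0.475 here) equal to the realised
truth proportions.

A thin CLI mirrors the pipeline stages for shell use:

```sh
exec/dkaudit simulate  --out cohort/ --seed 5
exec/dkaudit score     --in cohort/ --out scored/
exec/dkaudit aggregate --in cohort/ --out kpis.csv
exec/dkaudit report    --in cohort/ --out reports/
```

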