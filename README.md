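# telewalk

Analytics for home-based structured walking training in peripheral
arterial disease (PAD). Patients in a 12-week walking program submit
telehealth data — unsupervised app-based 6-minute walk tests (6MWT), daily
step counts, a daily 0–10 pain score and a 3-level well-being report —
alongside in-clinic baseline/end measurements (supervised 6MWT,
timed-up-and-go subtask times, subjective pain-free walking distance).
`telewalk` is for biostatisticians and digital-health researchers who want
to analyse such cohorts: it aggregates and normalises the weekly series,
computes adherence, correlation and pre/post reports, and predicts each
patient's **study-end 6MWT distance** week by week under leave-one-out
(LOO) evaluation.

Because no patient-level dataset of this kind is publicly deposited, the
package ships a seeded synthetic cohort generator calibrated to published
cohort summaries (pain declining 4.67 → 3.60, ≈ 4177 steps/day, pooled
same-day pain–distance correlation ≈ −0.39, ≈ 86% adherence), with latent
ground truth returned for recovery tests.

## Models

With `d_{n,i}` the week-`n` 6MWT level of patient `i` (carry-forward over
missing weeks) and `d_end,i` the supervised study-end distance:

* **Baseline reference** — `d̂ = d_{0,i}` (no improvement).
* **Average improvement** —
  `d̂_{n,i} = d_{n,i} + mean_{j≠i}(d_end,j − d_{n,j})`.
* **Individual log trend** — least-squares fit of `d = a ln x + b` to the
  patient's own tests at weeks `x ≤ n`, evaluated at `x = 12`; abstains
  with fewer than two distinct test weeks.
* **Pooled log trend** — per-patient mean-centred tests of all (other)
  patients pooled into one fit `(a_n, b_n)`;
  `d̂ = a_n ln 12 + b_n + d̄_i`.
* **Best-subset linear regression** — exhaustive search over in-clinic
  and telehealth feature subsets (≤ 4 by default), scored by LOO RMSE,
  with both pooled-grid ("grid") and within-fold ("honest") selection.

All models are compared by the root mean squared error (m) of the held-out
predictions, per week of prediction.

## Worked example

```r
library(telewalk)

cfg <- cohort_config(n_patients = 19, seed = 42)
ds  <- generate_cohort(cfg)

adh <- compute_adherence(ds$walktests)
round(100 * adh$overall, 2)
#> [1] 83.77

cc <- crosscorr_report(ds)
print(subset(cc, pair == "pain_vs_distance"), digits = 3)
#>               pair     r        p   method   n
#> 2 pain_vs_distance -0.37 2.79e-10 spearman 273

loo_evaluate(ds, "baseline", 0)$rmse   # no-improvement reference
#> [1] 125.5605
loo_evaluate(ds, "log_pool", 6)$rmse   # pooled log trend at week 6
#> [1] 36.74506
```

Read: patients performed on average 83.77% of the recommended weekly
tests; on days with both reports, more pain goes with shorter test
distances (Spearman r = −0.37 over 273 patient-days); and by week 6 the
pooled logarithmic trend predicts the study-end distance with a 37 m
error, against 126 m for assuming no improvement.

## Analysis workflow

The full analysis is a sequence of thin drivers over the package:

```sh
Rscript analysis/01_simulate.R    # 19-patient cohort -> results/cohort/
Rscript analysis/02_trends.R      # adherence, correlations, pre/post tables
Rscript analysis/03_predict.R     # per-patient LOO predictions
Rscript analysis/04_evaluate.R    # RMSE-by-week + feature-count sweep
```

Outputs land under `results/tables/` as CSV (`rmse_by_week.csv` is the
model-by-week table; `feature_sweep.csv` the best subset per feature
count).

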