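# markerstab

Bootstrap-stable biomarker prognostic models for censored survival data.

## What it is for

Immunohistochemistry panels yield dozens of candidate tissue biomarkers
(histoscores, 0–300) for predicting breast-cancer recurrence, but typical
cohorts are small (~400 patients, ~100 events), histoscore distributions are
right-skewed, effects are often nonlinear, and every marker has missing
values. Fitting one multivariable Cox model to such data overfits.
`markerstab` implements a four-step procedure for this setting, together with
evaluation machinery against the Nottingham Prognostic Index
(NPI = 0.2·size(cm) + grade + nodal stage) and a synthetic-cohort generator
with known ground truth:

1. **Screening & risk-function choice** — per variable, a fractional-
   polynomial closed test at level 0.1 (powers {−2, −1, 0 = log, 0.5, 1, 2, 3});
   failing that, a minimum-p cutpoint scan over the inner 80% of the
   distribution at the multiplicity-calibrated level 0.005; failing that,
   four non-ordinal quartile-range contrasts at 0.1/4 = 0.025.
2. **Imputation & resampling** — chained-equation multiple imputation
   (m = 10; predictive mean matching, proportional-odds draws for ordinal
   variables, event indicator + Nelson–Aalen cumulative hazard in every
   imputation model), frozen screened transformations applied, then B = 100
   bootstrap samples per completed data set (1000 sample data sets).
3. **Stability refinement** — threshold/non-ordinal forms re-scanned on every
   sample; per-sample multivariable-FP backward elimination (removal at
   P = 0.05, linear variables upgradable to FP forms); variables with
   inclusion frequency < 50% dropped as *unreliable*, retained variables with
   a wobbling risk-function class dropped as *unstable*.
4. **Aggregation** — final model refitted on each imputed data set, pooled by
   Rubin's rules (variance = within + (1 + 1/m)·between), hazard ratios per
   100 histoscore units, per-patient aggregate risk scores, and quartile (or
   tertile) risk groups.

Evaluation: Harrell's C-index, Nagelkerke R², group-wise Kaplan–Meier
event-free rates at 3/5/7/10 years, and risk-group reclassification against
NPI (net gain among events and event-free cases, exact binomial test among
movers).

## Worked example

Simulate a 401-patient cohort with six known effects (one per supported risk
function) plus 11 noise markers and realistic missingness, then run the
pipeline at reduced scale (m = 5, B = 40; ~1 minute):

```r
library(markerstab)
w   <- example_world()
cfg <- pipeline_config(m = 5, B = 40, seed = 1)
out <- simulate_and_run(w$cohort_config, w$model, cfg, seed = 1,
                        missing_spec = w$missing_spec)
print(out$report)
```

```
<run_report> RFS endpoint, status: ok
<stability_report> 200 sample models, threshold 50%
    variable inclusion_frequency form_stability         verdict
1  markerLin                99.5           84.9 reliable-stable
2  markerLog               100.0          100.0 reliable-stable
3    markerU                75.0          100.0 reliable-stable
4  markerThr                99.0           68.2 reliable-stable
5  markerNol                99.0           80.0 reliable-stable
6    noise10                68.0          100.0 reliable-stable
7    noise11                45.0           61.0      unreliable
8      nodal                75.0          100.0 reliable-stable
9      grade                 6.0          100.0      unreliable
10      size                12.5           92.0      unreliable
11       age                34.0           94.1      unreliable
<aggregated_model> pooled over m = 5 imputations
       term    hr lower  upper       p units
1 markerLin 1.929 1.497  2.487 3.9e-07     1
...
C-index 0.767 (NPI 0.548), Nagelkerke R2 0.219
```

Reading this: all six true effects pass the 50% inclusion rule (one noise
marker, `noise10`, sneaks in — the kind of false positive the stability rule
reduces but cannot eliminate); clinical variables without true effects are
dropped as unreliable. The fitted aggregate score discriminates almost as
well as the true generating score on this cohort (C-index 0.767 vs 0.762),
and far better than NPI (0.548, chance-level here because the generating
model gives size and grade no effect). Recovery diagnostics — inclusion
frequencies of true vs noise variables and pooled coefficients against the
generating truth — are in `out$diagnostics`.

The individual stages are exported (`screen_all`, `mice_impute`,
`make_sample_set`, `mfp_backward`, `inclusion_frequency`, `refine`,
`fit_final`, `rubin_pool`, `aggregate_scores`, `make_risk_groups`,
`npi_score`, `harrell_c`, `reclassify`, `event_free_rate`, ...) and operate
on plain data frames and matrices.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the full pipeline end-to-end on the study-shaped synthetic world at the
published scale (401 patients, m = 10 imputations × B = 100 bootstrap
samples = 1000 sample models), logs inclusion frequencies, the pooled model
and the discrimination metrics, and writes the acceptance JSON to `--out`.
All randomness derives from `--seed`.
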