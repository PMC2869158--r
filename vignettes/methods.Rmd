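---
title: "Bootstrap-stable biomarker prognostic modelling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bootstrap-stable biomarker prognostic modelling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Tissue-biomarker panels measured by immunohistochemistry (histoscores on a
0–300 scale) offer dozens of candidate predictors of breast-cancer
recurrence, but cohorts are modest (a few hundred patients, ~100 events),
histoscore distributions are strongly right-skewed, relationships with
outcome are often nonlinear, and every marker carries missing values. Naive
multivariable Cox modelling under these conditions overfits badly.
`markerstab` implements a four-step procedure that addresses each hazard in
turn, and evaluates the result against the Nottingham Prognostic Index
(NPI = 0.2·size(cm) + grade + nodal stage).

# The four steps

## Step 1 — screening and choice of risk function

Each candidate variable is screened univariately through a fixed cascade,
and the *form* in which it enters the log-hazard is chosen at the same time:

1. **Fractional polynomials.** The FP closed test at level 0.1: the best
   second-degree fractional polynomial (powers from
   {−2, −1, 0(log), 0.5, 1, 2, 3}; a repeated power p contributes
   (x^p, x^p log x)) is tested against the null (4 df), against the linear
   form (3 df), and against the best FP1 (2 df). Variables with fewer than
   10 distinct values (ordinal clinical variables) take a plain linear Cox
   test at 0.1 instead.
2. **Minimum-p threshold scan.** If the FP route selects nothing, every
   distinct observed value in the inner 80% of the empirical distribution is
   tried as a cutpoint (`x >= cut` vs below, log-rank test); the variable is
   selected if the minimum p falls below 0.005. The 0.005 level is the
   multiplicity-calibrated equivalent of a family level of about 0.1: the
   acceptance suite reproduces this by simulation (null selection rate
   9–10% at n = 400).
3. **Non-ordinal quartile contrasts.** Failing both, exactly four
   dichotomisations are tried — R2, R3, R2∪R3 and R1∪R3 against the rest,
   where R1..R4 are the quartile ranges — each at the Bonferroni level
   0.1/4 = 0.025.

All scalings (shift/scale before power transforms), cutpoints and quartiles
are *frozen* from the screening data and reused unchanged downstream.

Design choices the sources leave open, decided here: the per-cut test in the
scan is the log-rank test; the cutpoint grid is the inner 80% of the
distribution (both standard for maximally selected statistics); thresholds
are coded `>= cut`; the four non-ordinal patterns above are one concrete
reading of "two neighbouring quartile ranges vs the rest", chosen so an
interior-range effect (e.g. between the 2nd and 3rd quartile) is
recoverable; p-ties in the scan resolve to the smallest cutpoint.

## Step 2 — multiple imputation and bootstrap resampling

Missing covariate values are imputed by chained equations, m = 10 completed
data sets by default. Each variable's imputation model conditions on the
other candidates plus the event indicator and the Nelson–Aalen cumulative
hazard (the standard composition for survival outcomes, which the source
procedure does not spell out). Continuous variables use Bayesian-draw
predictive mean matching with 5 donors; ordinal variables a
proportional-odds draw (`MASS::polr`, with a PMM fallback when that fit
degenerates). Chains run 20 sweeps, visiting variables in order of
increasing missingness. Observed values are never modified, and with no
missingness the m data sets are identical copies. The frozen screened
transformations are then applied, and B = 100 bootstrap samples (simple case
resampling) are drawn from each completed data set: 1000 "sample" data sets,
each re-materialisable from `(master seed, imputation index, bootstrap
index)` alone.

## Step 3 — stability refinement

First, threshold and non-ordinal effects are re-scanned on every sample at
the screening levels; a special form that re-manifests in fewer than 50% of
samples drops its variable before modelling. The surviving candidates —
special forms as frozen 0/1 indicators, screened linear/FP variables, and
the four clinical variables (offered, never forced) — enter a
multivariable-FP backward elimination on each sample: likelihood-ratio
removal at P = 0.05 (one variable per cycle, the least significant), with
retained screened-linear continuous variables re-examined by the FP closed
test at 0.05, adjusted for the rest of the model, and upgraded to FP1/FP2
when warranted. A cycle here is "eliminate to convergence, then one FP pass",
iterated until nothing changes; this has the same fixed point as re-running
the FP test inside every elimination sweep at a fraction of the cost.
Ties are handled by the Efron approximation throughout; monotone-likelihood
fits are detected by a standardised-coefficient divergence check and treated
as failed fits, never silent estimates.

Inclusion frequencies over all m·B models drive the two 50% rules: a
variable retained in fewer than half the models is *unreliable*; a retained
continuous variable whose risk-function class (linear vs FP1 vs FP2, judged
among the models that retain it) or special form fails to re-manifest in
half is *unstable*. "At least 50%" is inclusive, so a frequency of exactly
0.5 passes. Only reliable, stable variables proceed, with their frozen
screened forms.

## Step 4 — aggregation

The final model is refitted on each completed data set and pooled by Rubin's
rules: coefficients averaged; variance = mean within-imputation variance +
(1 + 1/m) × between-imputation variance. Confidence intervals and p-values
use the normal approximation (no small-sample degrees-of-freedom adjustment;
documented and configurable through the pooling function). Hazard ratios for
raw-scale continuous biomarkers are reported per 100 histoscore units.
Each patient's aggregate risk score is the mean linear predictor across the
m models; the standardised score is its cohort z-score. Risk groups are
empirical quantile splits — quartiles for the recurrence-free-survival
design, tertiles for the on-treatment endpoint, which has fewer events —
with ties at a cutoff assigned to the lower group.

# Evaluation

Discrimination is Harrell's C (half credit for tied scores, tied event times
not comparable); predictive ability is Nagelkerke's max-rescaled R².
Risk-group reclassification against NPI cross-classifies patients
(quartile-vs-quartile using the NPI splits 3.3/4.2/4.8, or
tertile-vs-tertile), counts moves up and down separately among events and
event-free cases, reports the net gain in percent, and tests up-vs-down
among movers by an exact binomial test (the source reports p-values without
naming its test). Standard NPI grouping uses the conventional <3.4 /
3.4–5.4 / >5.4 cutoffs, which the source invokes without printing; they are
configurable. Kaplan–Meier event-free rates are reported per group at 3, 5,
7 and 10 years, with horizons beyond follow-up flagged rather than
extrapolated.

# The synthetic world

No real cohort is distributed, so validation runs on generated data
(`generate_cohort()`, `example_world()`). The generator emulates the stated
study structure: 401 patients; histoscores gamma-distributed
(shape 1.4, mean 90, truncated at 300 — positively skewed); nodal status and
grade ordinal 1–3; tumour size log-normal around 2.2 cm; age ~ N(61, 10²);
tamoxifen duration gamma with median 5 years, capped at 10. Survival times
come from inverse-transform sampling of an exponential baseline under
proportional hazards; censoring is the minimum of an independent exponential
(0.10/y) and a 10-year administrative horizon; the on-treatment endpoint
censors recurrence at tamoxifen cessation. The default baseline hazard of
`example_world()` (0.0206/y) was calibrated once, with
`calibrate_baseline()`, so the expected event fraction is 112/401 ≈ 0.28.
MCAR missingness of 1.2–9.2% (mean 5.2%) is placed on the biomarkers; an
optional MAR mechanism makes missingness logistic in a named fully observed
variable. The world contains one strong true effect of each supported form:
linear (β = 0.55 per 100 units), log/FP1(0) (−0.55), U-shaped FP2(1,2)
(−2.4, 0.8), a threshold at histoscore 104 (β = 1.0, the published HR ≈ 2.7
for a nuclear phospho-MAPK-like marker), a protective non-ordinal R3
contrast (−1.0), and linear nodal status (0.6, HR ≈ 1.8 as published).
Effect sizes follow published hazard-ratio magnitudes where available and
were otherwise fixed, before any acceptance run, so that each effect has
roughly 90% univariate screening power through its own route at this cohort
size; the weakest published magnitudes would otherwise make criterion-style
recovery checks a test of screening power rather than of the pipeline.

What the generator does **not** emulate: measurement error in image-derived
histoscores, tissue-microarray core sampling, correlated marker families,
accrual patterns, or informative censoring. A green recovery test therefore
establishes that the pipeline recovers effects of every supported form at
realistic size and missingness — not that it would perform identically on
real immunohistochemistry data.

# Numerical choices and degenerate inputs

Cox fitting delegates to `survival::coxph.fit` (Efron ties, Newton–Raphson,
tolerance 1e-9, ≤100 iterations); rank-deficient designs, <2 events and
diverging coefficients are explicit errors. Fits inside the bootstrap loop
that fail are logged as non-converged samples, not fatal. Imputation
regressions drop aliased columns and fall back to a ridge-stabilised
Cholesky when needed. The minimum-p scan skips cutpoints with zero log-rank
variance; a constant variable has no candidate cutpoints and is reported
unselected. Quartile degeneracy (ties emptying a non-ordinal range) skips
the affected patterns and is recorded. An empty final model, or a final
model with too few distinct scores to form the requested risk groups, is a
valid, flagged outcome.

# Known limitations

Two behaviours of the published procedure itself, reproduced faithfully
here, deserve emphasis:

* **Bootstrap duplication inflates re-scan statistics.** Re-running the
  minimum-p scan on a bootstrap sample treats duplicated rows as independent,
  so the log-rank statistics are anti-conservative: a pure-noise variable
  re-selects in roughly 60% of resamples, against a ~10% fresh-sample null
  rate. In the pipeline this only affects variables that already screened in,
  but it makes the 50% form-stability rule permissive.
* **Resampling cannot undo screening-selection bias.** A variable that
  screened in by chance on a given cohort exhibits the same spurious
  association in bootstrap resamples of that cohort, so its inclusion
  frequency often exceeds 50%. On all-noise cohorts at the study's own scale
  (20 candidates), the final model is therefore rarely empty — about one to
  four false variables survive. The corresponding acceptance check asserts
  the idealised claim and is intentionally left failing, as a documented
  property of the method rather than of the implementation.

Other limitations: no time-varying covariates, stratified baselines or
frailty terms; no shrinkage alternatives to backward elimination; no
external-validation or recalibration machinery; imputation assumes
missingness at random given the conditioning set.
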