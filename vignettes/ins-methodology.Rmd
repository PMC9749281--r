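---
title: "The inflammation-nutrition score: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The inflammation-nutrition score: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insmark)
```

## The problem

Systemic inflammation and malnutrition are intertwined drivers of poor
survival in cancer patients, and dozens of blood-based indices quantify one
or the other: ratio indices built from routine counts (NLR, PLR, SII, GLR,
LCR, CAR), ordinal scores (mGPS, LCS, CONUT), and albumin/weight-based
nutrition indices (ALI, PNI, NRI, GNRI, mGNRI, AGR). This package implements
a pipeline that turns such indices into a single ordinal risk
stratification, the inflammation-nutrition score (INS): rank the candidate
indices by prognostic discrimination, keep the top two inflammation and the
top two nutrition indices, dichotomize each at a survival-optimal threshold,
and count adverse components. With four components the count 0-4 maps to
strata INS 1-5.

The shipped default configuration (`ins2022_config()`) fixes the four
components and thresholds at their published values: low LCR (< 2813), high
CAR (>= 0.165), low ALI (< 33), low NRI (< 94), each scoring one point, with
stratum = points + 1. "Below" thresholds are strict and "at-or-above"
thresholds are closed, so a value exactly on a "below" boundary is not
adverse — the scorer tests this boundary bit-exactly.

## Canonical units and the index registry

The original report does not state the laboratory units underlying its
thresholds, so the data layer fixes one canonical unit per field (counts in
10^9/L, albumin and hemoglobin in g/L, CRP in mg/L, glucose and cholesterol
in mmol/L) and requires the ingestion schema to declare the source units
explicitly; conversion happens once, at ingestion. Each of the 15 formulas
then rescales internally where its published definition uses another scale:

* LCR is lymphocytes per microliter over CRP in mg/dL
  (`lymphocytes * 1000 / (crp / 10)`). This convention is the only one on
  which the published cutpoint 2813 is plausible: a typical patient with
  lymphocytes 1.5x10^9/L and CRP 5 mg/L scores 3000.
* PNI reduces to `albumin (g/L) + 5 x lymphocytes` in canonical units.
* NRI/GNRI/mGNRI cap the weight ratio `weight / ideal_weight` at 1
  (standard GNRI convention; the source is silent), with Lorentz ideal
  weight.
* mGPS uses CRP > 10 mg/L and albumin < 35 g/L; LCS awards one point each
  for lymphocytes < 1.0x10^9/L and CRP >= 10 mg/L. The LCS cutoffs and the
  exact mGNRI form are not defined in the source's main text, so both follow
  the standard literature forms and are exposed as options
  (`index_options()`).
* CONUT uses the original 0-12 scoring table (albumin g/dL, total
  lymphocytes/uL, cholesterol mg/dL).

All 15 formulas live in one registry keyed by index name, so a definitional
correction touches a single table. Missing optional labs (total protein,
cholesterol) make AGR/CONUT missing, never an error: they are comparison
indices, not INS components. Records without CRP are retained but flagged
ineligible for scoring, since two of the four components need CRP.

## Optimal stratification

Thresholds come from the maximally selected log-rank statistic:
`optimal_cutpoint()` scans every distinct observed value inside the
(0.10, 0.90) quantile window whose split leaves at least 10% of patients on
each side, computes the two-group log-rank chi-square for each split
(hypergeometric variance, so ties are handled exactly), and returns the
maximizing threshold, breaking ties toward the smaller value. The window
and minimum group fraction follow standard maximally-selected-statistic
practice to avoid degenerate tail splits; both are arguments. The adverse
side is read off the sign of observed-minus-expected deaths in the low
group, matching the "<" / ">=" orientation of the shipped components.

Because the threshold is chosen to maximize the statistic, the naive 1-df
p-value is anti-conservative under the null. It is reported as `p_naive`,
and a permutation-corrected p-value (biomarker permuted against outcomes,
seeded) is available via `n_perm`; the default skips it because the
pipeline uses the statistic for ranking, not for inference.

The scan is exhaustive but vectorized: two-dimensional histograms over
(event-time index, threshold position) are cumulated into per-threshold
at-risk and death counts, chunked over thresholds to bound memory. Tests
verify exact agreement with a split-by-split `survdiff` scan.

## Discrimination statistics

**Harrell's C** counts pairs where the shorter follow-up is an observed
event; tied risks count one half. The point estimate and
infinitesimal-jackknife variance are delegated to
`survival::concordance()`, which was verified to agree to machine precision
with direct pair enumeration under this pair-usability rule (the test suite
re-checks this on random censored datasets up to n = 200). Differences
between two scores on the same patients (`compare_c()`) use a paired
bootstrap over patients for the p-value.

**cNRI and IDI** (`cnri_idi()`) are computed at a fixed horizon, default 36
months. Risk scores are mapped to event probabilities at the horizon
through a univariable Cox fit and its baseline cumulative hazard
(`prob_map = "cox"`); pass probabilities directly with
`prob_map = "identity"`. Event/non-event status at the horizon is weighted
by inverse probability of censoring (IPCW), with weights `1/G(T-)` for
events and `1/G(t*)` for patients followed past the horizon, where `G` is
the Kaplan-Meier estimate of the censoring distribution. When no censoring
precedes the horizon every weight is 1 and the estimator reduces exactly to
the textbook binary-outcome definitions — the tests assert this reduction
to machine precision. The estimator choice is recorded in every report
because other cNRI/IDI estimators exist and give different numbers.

**Time-dependent AUC** (`time_dependent_auc()`) is the cumulative-case /
dynamic-control AUC with the same IPCW weighting: the probability that a
patient with an event by `t` carries a higher risk score than one
event-free past `t`. Without censoring it is the plain rank AUC at `t`.

**Cox models** are partial-likelihood fits through `survival::coxph()`.
The stratum enters as a categorical exposure against stratum 1; "model a"
is unadjusted and "model b" adds age, sex, BMI, TNM stage, tumor type,
surgery, radiotherapy, chemotherapy, hypertension, diabetes, smoking,
drinking and family history. The p-for-trend refits with the stratum as a
single ordinal term (the ordinal-score method). Fits warn below 10 events
per parameter and error on suspected monotone likelihood (|log HR| > 15).

**Dose-response** uses an authored restricted cubic spline basis
(truncated-power form with linear tails, normalized by the squared knot
span): 3 knots at the 0.10/0.50/0.90 quantiles give two columns, the linear
term and one nonlinear term; the nonlinearity p-value is the Wald test of
the nonlinear term and the hazard-ratio curve is referenced to the median.

**Screening** ranks indices by the concordance of their univariable Cox
linear predictor (so decreasing-risk indices are not penalized for their
direction), reports the Pearson correlation matrix, and retains the set
chosen by an L1-penalized Cox fit with seeded cross-validation
(`glmnet::cv.glmnet`, `lambda.min`). `select_top2_per_group()` takes the
top two per group, breaking exact C ties by registry order with a warning.

## The synthetic cohort

`simulate_cohort()` generates cohorts with the statistical structure the
INS analysis assumes, and known ground truth. One latent severity factor
(Beta(2,2) by default) drives every lab through log-scale regressions with
noise, so biomarkers are realistically collinear — the screening stage only
faces a meaningful task under correlation. Lab location/scale parameters
were chosen to land in clinically realistic ranges (lymphocytes ~0.3-4
x10^9/L, CRP log-normal with median ~6 mg/L, albumin ~25-55 g/L), which
also places the medians of LCR, CAR, ALI and NRI near the shipped
thresholds.

Survival is Weibull (shape 1.2, scale 260 months) with the hazard
multiplied by exp(log 1.43) per adverse component — chosen so the extreme
strata differ by a factor of about 1.43^4 ~ 4.2, the magnitude of the
unadjusted extreme-stratum hazard ratio in the motivating study — plus
stage (HR 1.20 per step) and age (HR 1.012 per year) effects, which create
genuine confounding between strata and covariates so that adjusted and
crude hazard ratios differ. Censoring is administrative (staggered entry
over 90 months against a 124-month closeout) plus exponential dropout at
0.002/month. These values were calibrated once so that roughly 45% of
patients die overall and stratum-wise death proportions rise monotonically
from the low twenties to around seventy percent at n = 5221.

What the simulator does **not** emulate: non-proportional hazards, real
tumor-type covariate structure, measurement batch effects, informative
censoring, or the flatter top-stratum mortality seen in real registry data
(a proportional-hazards generator with confounding necessarily overshoots
there). Passing recovery tests therefore demonstrates internal statistical
correctness of the pipeline, not clinical validity on any real cohort.

With `noise_scale = 0` the labs are deterministic functions of severity and
the ground-truth stratum equals rescoring the generated labs exactly — an
end-to-end identity the tests exercise. `make_changepoint_series()`
provides the single-biomarker step-hazard fixture for cutpoint recovery;
recovery is only expected when the true threshold lies inside the scan's
quantile window.

## Numerical choices and degenerate inputs

* Dichotomization at a "below" threshold is strict; the boundary value is
  not adverse. Cutpoint ties break toward the smaller threshold.
* Log-rank with all observations censored returns statistic 0 with a
  warning; a single group is an error.
* Zero denominators in index formulas yield missing values with a message,
  never errors; missing INS components invalidate the score rather than
  being imputed.
* The internal 7:3 split puts `round(0.7 n)` records in the training part.
  Exact split sizes are therefore deterministic given the seed.
* All resampling (bootstrap, CV folds, permutations) is seeded; the
  pipeline fans one run-level seed out to per-stage seeds by fixed offsets
  recorded in the manifest, so stages are reproducible independently.
* Function-level bootstrap defaults are B = 1000; the pipeline default is
  `n_boot = 200`, a pragmatic choice for interactive use on cohorts of a
  few thousand patients — raise it for publication-grade intervals.

## Validation problem sizes

The shipped test suite validates the scoring rule exhaustively over all
2^4 indicator patterns; the discrimination statistics against enumeration
oracles at n <= 200 (C), n <= 100 (cutpoint scan) and n = 300 (uncensored
cNRI/IDI/AUC reductions); threshold recovery on 50 seeded changepoint
series at n = 2000 and hazard ratio 2.5 (within +/-2 units in >= 90% of
seeds); Cox CI coverage over 200 seeded replicates; null calibration of
log-rank, trend and nonlinearity p-values over 200 replicates each; and the
full directional pattern — monotone stratum mortality, ordered
Kaplan-Meier curves, p-for-trend < 0.001, composite C at least each
component's C — on the default synthetic cohort of n = 5221.

## Worked example

```{r example, eval = FALSE}
library(insmark)
run <- run_pipeline(pipeline_config(
  input = list(simulate = list(n = 2000)),
  seed = 7, n_boot = 50))
print(run)
run$cutpoints$LCR
```

## Limitations

The package reproduces the construction and evaluation machinery, not any
cohort-dependent estimate: published hazard ratios, C-statistics and
mortality percentages depend on patient data that are not redistributable,
and the synthetic default is a structural stand-in. No competing risks, no
proportional-hazards diagnostics beyond the separation guard, no multiway
stratification, no imputation.
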