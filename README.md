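# insmark

Construction and evaluation of the inflammation-nutrition score (INS), an
ordinal prognostic stratification for cancer cohorts built from routine
blood labs, plus the full survival-evaluation battery around it.

## What it does

Systemic inflammation and malnutrition jointly drive cancer mortality, and
both are visible in routine bloodwork. `insmark`:

1. **computes 15 inflammation/nutrition indices** per patient from
   canonical-unit labs — LCR, CAR, NLR, SII, PLR, GLR, LCS, mGPS, mGNRI
   (inflammation) and ALI, PNI, NRI, GNRI, AGR, CONUT (nutrition);
2. **screens** them by univariable Cox concordance, Pearson collinearity
   and L1-penalized Cox, and selects the top two per group;
3. **derives survival-optimal thresholds** by the maximally selected
   log-rank statistic: the cutpoint c maximizing the two-group log-rank
   chi-square over all admissible splits x < c;
4. **builds the INS**: each adverse component scores one point, and

   stratum = 1 + Σᵢ 1{componentᵢ adverse},

   so four components give strata 1–5. The shipped `ins2022_config()` uses
   low LCR (< 2813), high CAR (≥ 0.165), low ALI (< 33), low NRI (< 94);
5. **evaluates discrimination**: Kaplan-Meier by stratum, Cox models
   (crude and covariate-adjusted) with p-for-trend, Harrell's C with paired
   bootstrap comparisons, continuous NRI and IDI at a horizon under IPCW,
   time-dependent AUC, and restricted-cubic-spline dose-response curves;
6. **simulates cohorts** with a latent-severity generator and known ground
   truth (true thresholds, per-patient stratum, step-hazard changepoint
   series) for method validation.

## Worked example

```r
library(insmark)
run <- run_pipeline(pipeline_config(
  input = list(simulate = list(n = 2000)),
  seed = 7, n_boot = 50))
print(run)
#> INS pipeline run (seed 7)
#>   n = 2000 eligible, configuration: derived
#>   deaths by stratum: 24.2% 33.6% 45.8% 55.0% 70.3%
#>   C (INS) = 0.661 (0.642-0.680); AUC(36) = 0.674
#>   Cox model b, p-for-trend 3.19e-27
run$cutpoints$LCR
#> Optimal cutpoint: 2464.82 (adverse side: below)
#>   max log-rank chi-square 217.688 (naive p 2.89e-49)
#>   1600 candidates in [459.019, 12930.3] (quantiles 0.10-0.90), n = 2000
```

Reading: on a simulated cohort of 2,000 patients the pipeline screened the
panel, selected the top two inflammation and nutrition indices, derived
their optimal cutpoints (here LCR at 2,465, low side adverse), scored every
patient, and found death proportions rising monotonically across strata
1→5 with a composite concordance of 0.661 and a strongly significant
dose-response trend in the adjusted Cox model.

Scoring with the shipped configuration instead:

```r
co  <- read_cohort(system.file("extdata", "synthetic_cohort_example.csv", package = "insmark"),
                   read_schema(system.file("extdata", "schema_example.yaml", package = "insmark")))
scd <- score_cohort(co, ins2022_config())
print(scd)
#> INS scoring (INS-2022)
#>   eligible: 40  ineligible: 0
#> stratum
#>  1  2  3  4  5
#>  9  7  7 12  5
```

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/insmark score --in cohort.csv --schema schema.yaml \
    --config ins2022.yaml --out scored.csv
```

(subcommands: `simulate`, `panel`, `score`, `cutpoints`, `run`).

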