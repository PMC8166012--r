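# spotsodium

Estimating 24-hour urinary sodium excretion — the reference measure of
dietary salt intake — from a single spot urine void. The package is
aimed at population-surveillance biostatisticians who need to develop,
cross-validate and benchmark spot-urine prediction equations when full
24-h collection is impractical.

It implements the complete methodology as a tested pipeline:

* **Synthetic cohorts** with the anthropometry and urine biochemistry of
  an adult Malaysian surveillance population (n = 768): log-normal urine
  marginals moment-matched to published means/SDs, a Gaussian copula for
  cross-covariate dependence, and measured 24-h sodium generated from a
  configurable true linear model plus noise, calibrated so raw spot-Na
  vs 24-h-Na correlation ≈ 0.22 and fitted-equation correlation ≈ 0.50.
* **Collection screening**: adult eligibility plus the four completeness
  rules (volume ≥ 500 mL, duration ≥ 20 h, no missing void, sex-specific
  24-h creatinine threshold), with ordered per-record failure labels.
* **Equation development**: 50:50 split, stepwise multiple linear
  regression (entry p 0.05 / removal p 0.10), double cross-validation
  via standardized-beta composite z-scores with shrinkage statistics
  (R²own − R²cross), and a pooled final fit gated on small shrinkage.
* **Validation**: Bland–Altman mean bias with 95% CI and limits of
  agreement (predicted − measured), Pearson correlations, and a
  comparison table against the Tanaka and INTERSALT equations with
  explicit unit conversions (mg ↔ mmol ↔ g salt; creatinine via
  113.12 g/mol).

The core linear model for 24-h sodium (mg/day) is

```
Na24 = b0 + b1·weight(kg) + b2·age²(y²) + b3·[male]
     + b4·spotNa(mg/L) + b5·spotCr(mg/dL) + b6·spotK(mmol/L)
```

with the published Malaysian coefficient set
(909.368, 24.052, −0.11, 538.38, 0.269, −5.469, 5.541) available as
`spot24_coefficients()`.

## Worked example

```r
library(spotsodium)

# one participant at the cohort-mean covariates
rec <- data.frame(
  sex = "M", age_y = 49.08, weight_kg = 66.60, height_m = 1.58,
  spot_na_mg_l = 2002.75, spot_cr_mg_dl = 96.34, spot_k_mmol_l = 37.65
)
predict_spot24(rec)
#> [1] 3005.113    # mg/day
convert_sodium(predict_spot24(rec), "mg_day", "g_salt_day")
#> [1] 7.632987    # g salt/day

sample_size_correlation(0.15, alpha = 0.05, power = 0.80)
#> [1] 346         # required subjects per development subgroup
```

The full workflow lives in `analysis/` as numbered drivers
(`01_simulate_cohort.R` … `04_validate_equations.R`), each a thin
narrative script over the package functions, writing its tables under
`results/`. A complete run at seed 20180301 prints:

```
Split 627 screened records into 314 / 313
Double cross-validation:
  R[1,1] = 0.565  R[1,2] = 0.543  shrinkage1 =  0.0240
  R[2,2] = 0.523  R[2,1] = 0.500  shrinkage2 =  0.0245
Final pooled equation: n = 627, R = 0.538
Agreement with measured 24-h sodium (mg/day), best first:
  spot24     bias     0.00 (  -82.17,    82.17)  LoA -2057.47 to  2057.47  r = 0.538
  intersalt  bias   268.81 (  177.75,   359.86)  LoA -2011.12 to  2548.73  r = 0.427
  tanaka     bias   576.45 (  476.74,   676.16)  LoA -1920.27 to  3073.16  r = 0.341
Raw spot sodium correlation 0.215 vs fitted equation 0.538
```

i.e. the refitted equation has (by construction) near-zero mean bias and
the highest correlation with measured sodium, the raw spot concentration
alone correlates only weakly, and the external Tanaka and INTERSALT
equations carry substantial positive bias on this population — the same
qualitative pattern reported for the real cohort. `run_full_pipeline()`
performs the identical sequence in one call and writes five stamped
artifacts (cohort CSV, screening log, equation JSON, validation report,
summary).

See `vignettes/spot-urine-sodium.Rmd` for the model, the generator's
assumptions and what the synthetic results do and do not demonstrate.

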