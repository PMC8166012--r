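---
title: "Developing and validating spot-urine equations for 24-hour sodium"
author: "spotsodium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and validating spot-urine equations for 24-hour sodium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotsodium)
```

## The problem

Twenty-four-hour urinary sodium excretion is the reference standard for
estimating dietary salt intake (a complete day's urine captures roughly
90% of the day's sodium), but full 24-h collection is burdensome and
error-prone at survey scale. The practical alternative is a single spot
urine void plus a prediction equation. This package implements the full
methodology for developing and validating such an equation on an adult
surveillance cohort: cohort simulation, collection screening, stepwise
equation development with double cross-validation, and Bland-Altman
agreement analysis against the established Tanaka and INTERSALT
estimators.

Because the underlying survey data are not publicly deposited, the
package ships a synthetic-cohort generator calibrated to the published
marginal summaries of a Malaysian adult cohort (n = 768). Everything
downstream — screening rules, regression machinery, cross-validation,
agreement statistics — operates identically on real records in the same
CSV layout.

## The model

The developed equation is an ordinary linear model for measured 24-h
sodium (mg/day):

$$\widehat{Na}_{24h} = b_0 + b_1\,\text{weight} + b_2\,\text{age}^2 +
b_3\,[\text{male}] + b_4\,Na_{spot} + b_5\,Cr_{spot} + b_6\,K_{spot}$$

with weight in kg, age in years (entering squared), spot sodium in mg/L,
spot creatinine in mg/dL and spot potassium in mmol/L. The published
coefficient set (909.368, 24.052, −0.11, 538.38, 0.269, −5.469, 5.541)
is available as `spot24_coefficients()`; equations refitted on new data
produce the same object and are evaluated by the same predictor,
`predict_spot24()`.

The comparison estimators follow their published forms exactly. Tanaka
scales the spot sodium-to-creatinine ratio by predicted 24-h creatinine
(PRCr, a linear function of age, weight and height in cm) through a
power law with exponent 0.392; INTERSALT is a sex-specific linear model
on spot concentrations in mmol/L, BMI and age. Both return mmol/day;
unit changes are always explicit (`convert_sodium()`,
`convert_creatinine()`), never folded into coefficients, because the
literature's unit mixtures (mg/L vs mmol/L sodium, mg/dL vs mmol/L
creatinine, mg vs mmol vs g-salt outputs) are the dominant source of
implementation error in this area.

Two Tanaka constants circulate in print: the canonical PRCr intercept
−2244.45 and a variant −224.45 that appears in some secondary tables.
The latter inflates PRCr by exactly 2020 and predicts implausible
creatinine excretion, so the canonical value is the default and the
printed variant is selectable (`variant = "as_printed"`) for audit;
which one a given validation study actually used is often not
recoverable from its text.

## The synthetic cohort

`generate_cohort()` draws records through a Gaussian copula with:

* **Marginals.** Right-skewed, non-negative urine measures (spot Na/K/Cr,
  24-h volume, 24-h K and Cr) are log-normal, moment-matched to the
  published mean/SD; a zero-truncated-normal alternative is available by
  the `dist` flag. Weight and height are normal; age is a truncated
  normal on [18, 98] whose latent parameters are solved so the realized
  mean/SD stay on target (plain truncation would shift the mean by about
  +0.7 y). Sampling is inverse-CDF throughout, so there are no point
  masses at bounds and the copula correlations survive the transforms.
* **Dependence.** The published tables give only marginals, so the
  latent correlation matrix (`default_copula()`) is a declared
  assumption: weight–height 0.45, male–height 0.50, male–weight 0.20,
  positive correlations (0.30–0.35) among the spot concentrations
  (shared hydration state) with negative correlations (−0.20 to −0.30)
  to 24-h volume (dilution), spot-to-24-h creatinine 0.28 (the value
  reported for the real cohort), and male–24-h-creatinine 0.30 (muscle
  mass).
* **Outcome.** Measured 24-h sodium is the true linear model
  (`true_model_spec()`, defaulting to the published coefficients) plus
  Gaussian noise. `noise_sd = 1100` mg/day is a one-time calibration
  constant: at that value a large simulated cohort shows a
  fitted-equation multiple R of about 0.49, a raw spot-Na correlation of
  about 0.21, and an overall SD of 24-h sodium of about 1265 mg/day —
  jointly matching the three corresponding published quantities (0.501,
  0.219, 1269) as closely as one constant can.
* **Flags.** `pregnant`, `fasting`, `kidney_disease` and `missing_void`
  are emitted `FALSE`: the generator emulates the already-eligible study
  population, and screening tests construct failures explicitly.

What the generator does **not** emulate: survey weights and geographic
stratification, ethnicity effects, diurnal spot-timing variability,
proportional (level-dependent) prediction bias, and any nonlinearity in
the spot-to-24-h relation. Passing tests therefore demonstrate that the
machinery is correct and calibrated under an idealized linear-Gaussian
cohort — not that the equation performs equivalently on real
populations. In particular the real equation's tendency to underestimate
high excretion (a documented property of spot equations generally) is
outside the generator's linear world. A small consequence of honest
marginals: roughly 15% of generated records legitimately fail the
completeness rules (mostly the male creatinine threshold of 6 mmol/day
against a 24-h creatinine distribution centred at 8.9 mmol/day), so a
768-record run develops its equation on about 630 screened records.

## Screening

A complete 24-h collection requires volume ≥ 500 mL, recorded duration
≥ 20 h, no missing void, and a sex-specific 24-h creatinine rule
(6 mmol/day men, 4 mmol/day women; g/day converted via 113.12 g/mol).
The creatinine clause is printed in some protocols as "creatinine
*below* threshold" being complete, which inverts standard practice (low
creatinine is the classic marker of an *incomplete* collection). The
default here is `exclude_below`; the literal reading is available as
`cr_rule_direction = "exclude_above"` so both conventions can be
audited. All failed rules are reported per record, in the printed rule
order, and screening satisfies a partition invariant (kept + excluded =
input, always). Spot urine is checked only for presence and
non-negativity — no quality criterion is applied to the spot specimen,
matching field practice.

## Equation development

Development follows the double cross-validation design:

1. **Split** the screened cohort 50:50 (seeded; sizes differ by ≤ 1).
   The per-group sample-size requirement comes from the Fisher-z
   calculation (`sample_size_correlation()`): detecting r = 0.15 at
   α = 0.05 and power 0.80 needs 346 subjects per group, using the
   truncate-then-add-3 convention of the standard calculators.
2. **Select** predictors in each subgroup by bidirectional stepwise
   regression on p-values. Candidates are sex, weight, height, age², and
   the spot panel; age enters as age² by default (the published model's
   form — a flag adds linear age). Thresholds default to entry 0.05 /
   removal 0.10: the stated "5% significance" fixes entry, and the
   removal threshold follows the convention of the era's statistical
   software; requiring removal > entry also guarantees termination.
3. **Cross-validate.** With the union of the two selections, each
   group's standardized beta weights are applied to both groups as
   composite z-scores; R[h,g] is the correlation of group h's composite
   under group g's weights with group h's outcome, and shrinkage is
   R[own]² − R[cross]² within each group. Predictors are z-scored by the
   target group's own mean/SD (the natural reading of "each composite z
   score"; source-group standardization is a flag). Identical groups
   give exactly zero shrinkage; same-model halves give small positive
   values, with expectation approximately 2p(1−R²)/n — about 0.02 at
   n ≈ 400 per half with six predictors, and about 0.005 at n = 2000.
4. **Finalize.** If both |shrinkage| values are below the threshold
   (default 0.05 — the source literature says only "small", so this is a
   declared choice), the equation is refitted on the pooled cohort;
   otherwise `finalize_equation()` refuses with a diagnostic
   (overridable), which is exercised in tests by generating the halves
   from different true models.

`fit_ols()` itself delegates to R's QR-based least squares and reports
b, SE, two-sided t-tests on n − p − 1 df, standardized betas
(β = b·SD(x)/SD(y)), multiple R and residual SD. The test suite holds it
against an independently coded normal-equations oracle on random
designs, and standardized betas are recomputed rather than trusted from
any printed table (whose β column is not always consistent with its own
unstandardized coefficients and SDs).

## Agreement validation

`bland_altman()` fixes the difference direction as predicted − measured.
Limits of agreement are bias ± k·SD(d) and the bias CI is
bias ± k·SD(d)/√n. The default multiplier is k = 1.96 (z convention)
because back-calculating the published agreement table reproduces its CI
half-width almost exactly under z (71.71 vs the printed 71.91) and less
well under t; a t-quantile option is provided since the original
software's exact convention is not recoverable. Two internal identities
are property-tested for every input: the LoA midpoint equals the mean
bias, and the LoA width equals 2k·SD(d). `compare_equations()` runs any
named set of mg/day estimators over a cohort, skips records an estimator
cannot handle (e.g. a Tanaka domain error when PRCr ≤ 0) with a logged
reason, and orders rows by |mean bias|.

On synthetic cohorts only one correlation ordering is asserted: the
fitted equation must beat raw spot sodium (the published pattern
0.219 → 0.501). The relative ranking of Tanaka vs INTERSALT correlations
depends on generator details the published marginals do not pin down, so
it is reported but not asserted.

## Numerical and design choices

* Sample SD (n − 1) everywhere; a single-record summary reports SD 0 by
  convention.
* All randomness flows through per-call seeds (`with_seed()` restores
  the caller's RNG state); identical config + seed gives byte-identical
  output files, including the equation JSON.
* Cohort CSV I/O round-trips doubles exactly (shortest round-trip
  representation); heights > 3 on read are rejected as
  centimetre-entry errors, since the record contract stores metres.
* Sodium constants are exact: 23 mg/mmol, 2.54/1000 g-salt per mg;
  creatinine molar mass 113.12 g/mol.
* Degenerate inputs fail loudly and early: rank-deficient designs name
  the collinear columns, zero spot creatinine names the division, a
  negative power-law base names the domain problem, and unknown units
  are errors rather than guesses.

## Problem sizes used in the tests

Calibration and recovery checks simulate 5 000-record cohorts (every
generating coefficient recovered within 3 SE; every marginal mean within
3 SE of target). The double-cross-validation stability property uses 50
replicates at 2 000 per half (mean |shrinkage| < 0.02) plus 100
replicates at 400 per half, the study's own scale, where the expected
shrinkage from the formula above sits right at ~0.02. End-to-end runs
use the study's n = 768.

## Limitations

The package validates an equation against the same synthetic world that
generated it; it cannot certify performance on external populations, and
neither could the original design (no external validation cohort). The
stepwise-by-p-value procedure is reproduced because it is the method
under study, not because it is recommended practice today; users fitting
new equations on real data may prefer to compare against penalized or
information-criterion selection before fielding an equation.
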