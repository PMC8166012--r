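#!/usr/bin/env Rscript
# Develop the spot-urine prediction equation: split the screened cohort
# 50:50, select predictors by stepwise regression in each subgroup,
# double cross-validate the shared predictor set (composite z-scores,
# shrinkage statistics), and — if the shrinkage is small — fit the final
# pooled equation. Writes results/equation.json and results/dev_report.txt.

library(spotsodium)

seed <- 20180301
kept <- read_cohort("results/cohort_screened.csv")

n_req <- sample_size_correlation(0.15, alpha = 0.05, power = 0.80)
message(sprintf(
  "Required sample size per subgroup for r = 0.15 (alpha 0.05, power 0.80): %d",
  n_req
))

halves <- split_cohort(kept, seed = seed)
message(sprintf(
  "Split %d screened records into %d / %d",
  nrow(kept), nrow(halves$group1), nrow(halves$group2)
))

candidates <- c(
  "male", "weight_kg", "height_m", "age2",
  "spot_na_mg_l", "spot_cr_mg_dl", "spot_k_mmol_l"
)
sel1 <- stepwise_select(
  halves$group1$na24_mg,
  spotsodium:::design_columns(halves$group1, candidates)
)
sel2 <- stepwise_select(
  halves$group2$na24_mg,
  spotsodium:::design_columns(halves$group2, candidates)
)
message("Subgroup 1 retains: ", paste(sel1$terms, collapse = ", "))
message("Subgroup 2 retains: ", paste(sel2$terms, collapse = ", "))

labels <- union(sel1$terms, sel2$terms)
cv <- double_cross_validate(halves$group1, halves$group2, labels)
print(cv)

pooled_sel <- stepwise_select(
  kept$na24_mg, spotsodium:::design_columns(kept, candidates)
)
final <- finalize_equation(kept, pooled_sel$terms, cv = cv)
message("Final pooled equation:")
print(final$fit)

cfg <- pipeline_config(seed = seed, n = nrow(kept), outdir = "results")
spotsodium:::write_equation(final, cfg, "results/equation.json")

rpt <- file("results/dev_report.txt", "w")
writeLines(sprintf("seed: %d", seed), rpt)
writeLines(sprintf("required n per subgroup (r = 0.15): %d", n_req), rpt)
writeLines(sprintf(
  "split: %d / %d", nrow(halves$group1), nrow(halves$group2)
), rpt)
writeLines(sprintf(
  "R11 %.4f R12 %.4f R22 %.4f R21 %.4f shrinkage %.4f / %.4f",
  cv$R11, cv$R12, cv$R22, cv$R21, cv$shrinkage1, cv$shrinkage2
), rpt)
writeLines(sprintf("pooled multiple R: %.4f (n = %d)", final$fit$r, final$fit$n), rpt)
close(rpt)
message("Wrote results/equation.json and results/dev_report.txt")
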