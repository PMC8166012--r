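#!/usr/bin/env Rscript
# Validate the developed equation against measured 24-h sodium and compare
# it with the Tanaka and INTERSALT equations: Bland-Altman mean bias with
# limits of agreement, and Pearson correlations.
# Reads results/cohort_screened.csv + results/equation.json; writes
# results/validation_report.csv.

library(spotsodium)

kept <- read_cohort("results/cohort_screened.csv")
eq <- read_equation("results/equation.json")

tab <- compare_equations(kept, standard_estimators(spot24 = eq))
message("Agreement with measured 24-h sodium (mg/day), best first:")
for (i in seq_len(nrow(tab))) {
  message(sprintf(
    "  %-10s n = %4d  bias %8.2f (%8.2f, %8.2f)  LoA %8.2f to %8.2f  r = %.3f",
    tab$equation[i], tab$n[i], tab$mean_bias[i], tab$ci_low[i], tab$ci_high[i],
    tab$loa_low[i], tab$loa_high[i], tab$pearson_r[i]
  ))
}

raw <- pearson_r(kept$spot_na_mg_l, kept$na24_mg)
message(sprintf(
  "Raw spot sodium correlation %.3f vs fitted equation %.3f",
  raw$r, tab$pearson_r[tab$equation == "spot24"]
))

readr::write_csv(tab, "results/validation_report.csv")
message("Wrote results/validation_report.csv")
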