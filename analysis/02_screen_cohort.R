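#!/usr/bin/env Rscript
# Screen the simulated cohort: adult eligibility, 24-h collection
# completeness (volume >= 500 mL, duration >= 20 h, no missing void,
# sex-specific creatinine rule) and spot-urine availability.
# Reads results/cohort.csv; writes results/cohort_screened.csv and
# results/screening_log.csv.

library(spotsodium)

cohort <- read_cohort("results/cohort.csv")
res <- screen_cohort(cohort, completeness_criteria())
print(res)

write_cohort(res$kept, "results/cohort_screened.csv",
  comment = "screened cohort (eligible, complete 24-h collection, spot available)"
)
readr::write_csv(res$excluded, "results/screening_log.csv")
message("Wrote results/cohort_screened.csv and results/screening_log.csv")
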