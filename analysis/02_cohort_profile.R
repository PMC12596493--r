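#!/usr/bin/env Rscript
# Cohort multimorbidity profile: counts and percentages of single-disease,
# multimorbid (>= 2 diseases) and complex-multimorbid (>= 4) inpatients,
# overall, per sex, and per sex-age stratum, plus male/female fold ratios.

library(multimorbnet)

records <- read_records("results/data/cohort.csv")
records <- filter_scope(select_baseline(records))

strata <- c(stratify(records, "all"), stratify(records, "sex"),
            stratify(records, "sex_age"))
profiles <- profile_table(strata)

dir.create("results", showWarnings = FALSE)
write.table(profiles, "results/cohort_profile.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

m <- profiles[profiles$stratum == "male", ]
f <- profiles[profiles$stratum == "female", ]
cat(sprintf("multimorbidity: male %.2f%%, female %.2f%%, fold %.2f\n",
            m$pct_multi, f$pct_multi,
            prevalence_ratio(m$pct_multi, f$pct_multi)))
cat("wrote results/cohort_profile.tsv\n")
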