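#!/usr/bin/env Rscript

# Stage 3 — descriptive characteristics by balance-alteration group.
#
# Produces the cohort characteristics table (mean ± SD or n (%), two-group
# comparison p-values under the t / Mann-Whitney / chi-square policy).

library(copbalance)

cohort <- read.csv("scratch/study/cohort.csv")
tab1 <- table_one(cohort,
                  vars = c("age", "sex", "multimorbidity", "polypharmacy",
                           "falls_last_year", "bmi", "gait_speed", "squats"))

dir.create("results", showWarnings = FALSE)
write.csv(tab1, "results/table1.csv", row.names = FALSE)
print(tab1, row.names = FALSE)
cat("-> results/table1.csv\n")
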