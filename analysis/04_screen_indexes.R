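#!/usr/bin/env Rscript

# Stage 4 — screen all 78 sway indexes against the endpoint.
#
# Per index: group means ± SD, comparison p-value, AUC with DeLong CI;
# sorted by AUC descending. The top of this table identifies the index
# carried into the risk model.

library(copbalance)

dir <- "scratch/study"
cohort <- read.csv(file.path(dir, "cohort.csv"))
metrics <- read.csv(file.path(dir, "metrics_wide.csv"))

scr <- screen_indexes(metrics[, setdiff(names(metrics), "subject_id")],
                      cohort$balance_alteration)

dir.create("results", showWarnings = FALSE)
write.csv(scr, "results/index_screen.csv", row.names = FALSE)
cat("Indexes with a group difference at p < 0.05:",
    sum(scr$p_value < 0.05, na.rm = TRUE), "of", nrow(scr), "\n")
cat("Top 10 by AUC:\n")
print(head(scr[, c("index", "p_value", "auc", "auc_lo", "auc_hi")], 10),
      row.names = FALSE, digits = 3)
cat("-> results/index_screen.csv\n")
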