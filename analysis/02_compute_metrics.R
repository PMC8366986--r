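#!/usr/bin/env Rscript

# Stage 2 — sway metrics from the raw recordings.
#
# Reads every recording file written by stage 1, computes the 39 sway
# indexes per eye condition (78 per subject) and writes the wide metric
# table. This is the computation the acquisition device performs on-board
# after each test.

library(copbalance)

dir <- "scratch/study"
cohort <- read.csv(file.path(dir, "cohort.csv"))

metrics <- do.call(rbind, lapply(cohort$subject_id, function(id) {
  oe <- read_cop_recording(file.path(dir, "recordings", paste0(id, "_OE.csv")))
  ce <- read_cop_recording(file.path(dir, "recordings", paste0(id, "_CE.csv")))
  compute_all_metrics(oe, ce)
}))
metrics <- cbind(subject_id = cohort$subject_id, as.data.frame(metrics))

write.csv(metrics, file.path(dir, "metrics_wide.csv"), row.names = FALSE)
cat("Metric table:", nrow(metrics), "subjects x", ncol(metrics) - 1,
    "indexes ->", file.path(dir, "metrics_wide.csv"), "\n")
cat(sprintf("MVELAPOE pooled mean +- SD: %.2f +- %.2f mm/s\n",
            mean(metrics$MVELAPOE), sd(metrics$MVELAPOE)))
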