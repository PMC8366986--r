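#!/usr/bin/env Rscript

# Stage 1 — materialize the synthetic study.
#
# Generates the default synthetic cohort (n = 414, 115 with / 299 without a
# balance alteration) and writes every subject's raw open- and closed-eyes
# CoP recording plus the cohort table under scratch/study/. Downstream
# stages work purely from these files, mirroring an analysis that starts
# from the device's labelled recording files.

library(copbalance)

cfg <- generator_config(seed = 1)
dir <- "scratch/study"

cat("Generating cohort (n =", cfg$n_subjects, ") and",
    2 * cfg$n_subjects, "recordings ...\n")
generate_study_files(cfg, dir)

cohort <- read.csv(file.path(dir, "cohort.csv"))
cat("Cohort written:", nrow(cohort), "subjects;",
    sum(cohort$balance_alteration), "with balance alteration.\n")
cat("Recordings written:", length(list.files(file.path(dir, "recordings"))),
    "files under", file.path(dir, "recordings"), "\n")
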