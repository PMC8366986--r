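#!/usr/bin/env Rscript

# Stage 5 — Youden cut-off and the adjusted logistic risk model.
#
# Takes the top-AUC index from the screen, selects its Youden-optimal
# cut-off, dichotomizes, and fits the adjusted logistic model
# (dichotomized index + sex + age + BMI) with Hosmer-Lemeshow calibration
# and model AUC; finishes with the sample-size planning computation and two
# worked risk predictions.

library(copbalance)

dir <- "scratch/study"
cohort <- read.csv(file.path(dir, "cohort.csv"))
metrics <- read.csv(file.path(dir, "metrics_wide.csv"))
scr <- read.csv("results/index_screen.csv")

best <- scr$index[1]
cat("Best-discriminating index:", best, "\n")
roc <- roc_curve(metrics[[best]], cohort$balance_alteration)
cat(sprintf("  AUC = %.3f (%.3f-%.3f)\n", roc$auc,
            auc_ci(roc)[1], auc_ci(roc)[2]))

cut <- youden_cutoff(roc)
print(cut)

model_data <- data.frame(
  mvelap_dic = as.numeric(dichotomize(metrics[[best]], cut$cutoff)),
  sex_woman = as.numeric(cohort$sex == "woman"),
  age = cohort$age,
  bmi = cohort$bmi,
  balance_alteration = cohort$balance_alteration)
fit <- fit_logistic(model_data)
print(fit)

write.csv(fit$coefficients, "results/model_coefficients.csv", row.names = FALSE)

plan <- cochran_sample_size(p = 0.404, d = 0.05)
print(plan)

cat(sprintf("Fitted-model risk, man aged 70, BMI 22.7, below cut-off: %.2f%%\n",
            100 * predict_probability(fit, 0, 0, 70, 22.7)))
cat(sprintf("Fitted-model risk, woman aged 80, BMI 33.2, above cut-off: %.2f%%\n",
            100 * predict_probability(fit, 1, 1, 80, 33.2)))
cat("-> results/model_coefficients.csv\n")
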