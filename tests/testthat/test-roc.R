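test_that("trapezoid AUC matches hand-counted pairs and the usual limits", {
  r <- roc_curve(c(1, 3, 2, 4), c(0, 0, 1, 1))
  expect_equal(r$auc, 0.75)  # 3 wins, 1 loss over the 4 pos-neg pairs

  perfect <- roc_curve(c(1, 2, 10, 11), c(0, 0, 1, 1))
  expect_equal(perfect$auc, 1)

  set.seed(43)
  null <- roc_curve(rnorm(10000), rbinom(10000, 1, 0.5))
  expect_equal(null$auc, 0.5, tolerance = 0.02)

  expect_error(roc_curve(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("ROC thresholds are midpoints with sentinels and sensitivity is monotone", {
  r <- roc_curve(c(5, 7, 7, 9), c(0, 1, 0, 1))
  expect_equal(r$curve$threshold, c(Inf, 8, 6, -Inf))
  expect_true(all(diff(r$curve$sensitivity) >= 0))
  expect_true(all(diff(r$curve$specificity) <= 0))
})

test_that("trapezoid AUC equals the pair-counting oracle on random instances", {
  set.seed(47)
  for (i in 1:200) {
    n <- sample(6:60, 1)
    scores <- round(rnorm(n), sample(0:2, 1))  # coarse rounding forces ties
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (sum(labels) == 0 || sum(labels) == n) next
    r <- suppressWarnings(roc_curve(scores, labels))
    expect_equal(r$auc, auc_by_pairs(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone transforms and flips with labels", {
  set.seed(53)
  scores <- rlnorm(200)
  labels <- rbinom(200, 1, 0.4)
  a0 <- suppressWarnings(roc_curve(scores, labels)$auc)
  expect_equal(suppressWarnings(roc_curve(log(scores), labels)$auc), a0)
  expect_equal(suppressWarnings(roc_curve(scores^2, labels)$auc), a0)
  expect_equal(suppressWarnings(roc_curve(scores, 1 - labels)$auc), 1 - a0,
               tolerance = 1e-12)
})

test_that("the Youden cut-off maximizes J over every candidate threshold", {
  set.seed(59)
  for (i in 1:50) {
    n <- sample(8:50, 1)
    scores <- round(runif(n, 0, 10), 1)
    labels <- rbinom(n, 1, 0.5)
    if (sum(labels) == 0 || sum(labels) == n) next
    roc <- suppressWarnings(roc_curve(scores, labels))
    cut <- suppressWarnings(youden_cutoff(roc))
    # exhaustive J over a fine grid of candidate thresholds
    grid <- sort(unique(c(scores - 0.05, scores + 0.05, cut$cutoff)))
    j_grid <- vapply(grid, function(th) {
      sens <- mean(scores[labels == 1] >= th)
      spec <- mean(scores[labels == 0] < th)
      sens + spec - 1
    }, numeric(1))
    expect_gte(cut$youden_j + 1e-12, max(j_grid))
    expect_equal(cut$youden_j, cut$sensitivity + cut$specificity - 1,
                 tolerance = 1e-12)
  }
})

test_that("Youden ties resolve toward the most sensitive cut-off", {
  # perfect separation: the single midpoint attains J = 1
  roc <- roc_curve(c(1, 2, 8, 9), c(0, 0, 1, 1))
  cut <- youden_cutoff(roc)
  expect_equal(cut$cutoff, 5)
  expect_equal(cut$youden_j, 1)

  # anti-predictive marker is reported with a warning and J <= 0
  roc_flip <- suppressWarnings(roc_curve(c(1, 2, 8, 9), c(1, 1, 0, 0)))
  expect_warning(cut2 <- youden_cutoff(roc_flip), "does not separate")
  expect_lte(cut2$youden_j, 0)
})

test_that("the equal-variance binormal cut-off converges to the mean midpoint", {
  set.seed(61)
  scores <- c(rnorm(2e5, 10.88, 5.5), rnorm(2e5, 15.35, 5.5))
  labels <- rep(c(0, 1), each = 2e5)
  cut <- youden_cutoff(roc_curve(scores, labels))
  # argmax of the empirical J converges slowly; 0.5 covers its spread at this n
  expect_lt(abs(cut$cutoff - (10.88 + 15.35) / 2), 0.5)
})

test_that("confusion statistics reproduce the published dichotomized-marker rates", {
  cs <- confusion_stats(tp = 57, fp = 49, tn = 250, fn = 58)
  expect_equal(round(cs$sensitivity, 3), 0.496)
  expect_equal(round(cs$specificity, 3), 0.836)
  expect_equal(round(cs$ppv, 3), 0.538)
  expect_equal(round(cs$npv, 3), 0.812)

  # the dichotomized marker's trapezoid AUC is (sens + spec) / 2
  scores <- rep(c(1, 0, 1, 0), c(57, 58, 49, 250))
  labels <- rep(c(1, 1, 0, 0), c(57, 58, 49, 250))
  expect_equal(roc_curve(scores, labels)$auc,
               (cs$sensitivity + cs$specificity) / 2, tolerance = 1e-12)
  expect_equal(roc_curve(scores, labels)$auc, 0.666, tolerance = 0.0005)

  expect_equal(confusion_stats(1, 0, 1, 0),
               list(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))
  expect_true(is.na(confusion_stats(0, 0, 3, 2)$ppv))
  expect_error(confusion_stats(0, 0, 0, 0), "zero")
  expect_error(confusion_stats(-1, 0, 1, 1), "non-negative")
})

test_that("dichotomization is inclusive at the boundary", {
  expect_equal(dichotomize(c(14.23, 14.24, 14.25), 14.24),
               c(FALSE, TRUE, TRUE))
  expect_false(any(dichotomize(c(1, 2, 3), 10)))
  expect_error(dichotomize(1:3, Inf), "finite")
})

test_that("DeLong intervals agree with an independent implementation and shrink", {
  skip_if_not_installed("pROC")
  set.seed(67)
  for (i in 1:5) {
    scores <- rnorm(150) + rep(c(0, 1), c(80, 70))
    labels <- rep(c(0, 1), c(80, 70))
    roc <- roc_curve(scores, labels)
    ci <- auc_ci(roc)
    ref <- pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE,
                                  direction = "<"))
    expect_equal(roc$auc, as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                         quiet = TRUE,
                                                         direction = "<"))),
                 tolerance = 1e-12)
    expect_equal(ci[1], ref[1], tolerance = 1e-9)
    expect_equal(ci[2], ref[3], tolerance = 1e-9)
  }

  width <- function(n) {
    scores <- c(rnorm(n), rnorm(n, 1))
    labels <- rep(c(0, 1), each = n)
    diff(auc_ci(roc_curve(scores, labels)))
  }
  set.seed(71)
  w_small <- mean(replicate(20, width(100)))
  w_large <- mean(replicate(20, width(1600)))
  expect_lt(abs(w_small / w_large - 4), 0.6)  # 1/sqrt(n) scaling

  # separated classes at scale: interval collapses at the top
  sep <- roc_curve(c(rnorm(500), rnorm(500) + 100), rep(c(0, 1), each = 500))
  expect_warning(ci <- auc_ci(sep), "degenerate")
  expect_equal(ci, c(1, 1))
})

test_that("DeLong intervals achieve near-nominal coverage", {
  set.seed(73)
  true_auc <- pnorm(1 / sqrt(2))  # N(0,1) vs N(1,1)
  hits <- replicate(500, {
    scores <- c(rnorm(100), rnorm(100, 1))
    labels <- rep(c(0, 1), each = 100)
    ci <- auc_ci(roc_curve(scores, labels))
    ci[1] <= true_auc && true_auc <= ci[2]
  })
  expect_lt(abs(mean(hits) - 0.95), 0.03)
})

test_that("index screening ranks the panel by AUC with group summaries", {
  set.seed(79)
  n <- 200
  endpoint <- rbinom(n, 1, 0.4)
  metrics <- data.frame(
    good = rnorm(n, mean = endpoint),          # informative
    noise = rnorm(n),                          # null
    flat = rep(1, n))                          # degenerate
  scr <- screen_indexes(metrics, endpoint, adjust = TRUE)
  expect_equal(scr$index[1], "good")
  expect_true(all(diff(scr$auc) <= 0))
  expect_lt(scr$p_value[scr$index == "good"], 0.001)
  expect_equal(scr$auc[scr$index == "flat"], 0.5)
  expect_true(all(scr$p_adj_bh >= scr$p_value, na.rm = TRUE))
})
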