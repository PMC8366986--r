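#' ROC curve with trapezoid AUC
#'
#' Builds the empirical ROC curve of a continuous marker against a binary
#' endpoint. The positive-class convention is higher score = higher risk: a
#' subject is called positive when `score >= threshold`. Candidate
#' thresholds are the midpoints between consecutive distinct scores plus
#' `-Inf`/`+Inf` sentinels, so the curve never depends on the raw data
#' values themselves. The AUC is the trapezoid area under (1-specificity,
#' sensitivity), which on these thresholds equals the Mann-Whitney
#' pair-counting estimate (ties counted 1/2).
#'
#' @param scores Numeric marker values.
#' @param labels Binary endpoint (logical, 0/1, or two-level factor);
#'   `TRUE`/1 = condition present.
#' @return An object of class `cop_roc`: `curve` (data frame `threshold`,
#'   `sensitivity`, `specificity`, thresholds decreasing), `auc`, `n_pos`,
#'   `n_neg`, and the input `scores`/`labels` (used by [auc_ci()] and
#'   [youden_cutoff()]).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as_binary(labels, "labels")
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present in `labels`", call. = FALSE)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  last_of_run <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(l)[last_of_run]
  fp <- cumsum(!l)[last_of_run]
  u <- s[last_of_run]                     # distinct scores, decreasing
  k <- length(u)
  thr <- c(Inf, (u[-1] + u[-k]) / 2, -Inf)
  sens <- c(0, tp[-k] / n_pos, 1)         # P(score >= thr | positive)
  spec <- c(1, 1 - fp[-k] / n_neg, 0)
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  if (auc < 0.5) {
    warning("AUC below 0.5: the marker is anti-predictive under the ",
            "higher-score-is-positive convention", call. = FALSE)
  }
  structure(
    list(curve = data.frame(threshold = thr, sensitivity = sens,
                            specificity = spec),
         auc = auc, n_pos = n_pos, n_neg = n_neg,
         scores = scores, labels = labels),
    class = "cop_roc")
}

#' @export
print.cop_roc <- function(x, ...) {
  cat(sprintf("<cop_roc> AUC = %.4f (%d positive / %d negative, %d thresholds)\n",
              x$auc, x$n_pos, x$n_neg, nrow(x$curve)))
  invisible(x)
}

#' Confidence interval for the AUC
#'
#' DeLong's variance estimate from the midrank placements of positives
#' among negatives and vice versa (the default), or the Hanley-McNeil
#' exponential approximation. The Wald interval is clipped to \[0, 1\].
#'
#' @param roc A [roc_curve()] result.
#' @param level Confidence level (default 0.95).
#' @param method `"delong"` (default) or `"hanley"`.
#' @return Numeric vector `c(low, high)`.
#' @export
auc_ci <- function(roc, level = 0.95, method = c("delong", "hanley")) {
  stopifnot(inherits(roc, "cop_roc"))
  method <- match.arg(method)
  x <- roc$scores[roc$labels]   # positives
  y <- roc$scores[!roc$labels]  # negatives
  m <- length(x); n <- length(y)
  auc <- roc$auc
  v <- if (method == "delong") {
    r_all <- rank(c(x, y))
    v10 <- (r_all[seq_len(m)] - rank(x)) / n        # placement of each positive
    v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m
    stats::var(v10) / m + stats::var(v01) / n
  } else {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    (auc * (1 - auc) + (m - 1) * (q1 - auc^2) + (n - 1) * (q2 - auc^2)) / (m * n)
  }
  if (v <= 0) {
    warning("degenerate AUC variance; interval collapses to the point estimate",
            call. = FALSE)
    return(c(auc, auc))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  pmin(1, pmax(0, c(auc - z * sqrt(v), auc + z * sqrt(v))))
}

#' Youden-optimal cut-off and its confusion statistics
#'
#' Selects the threshold maximizing Youden's statistic
#' `J = sensitivity + specificity - 1`, breaking ties toward the lowest
#' cut-off (the most sensitive rule). The selected cut-off is applied with
#' the inclusive convention `positive = score >= cutoff`.
#'
#' @param roc A [roc_curve()] result.
#' @return An object of class `cop_cutoff`: `cutoff`, `youden_j`, counts
#'   `tp`/`fp`/`tn`/`fn`, and the [confusion_stats()] rates.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "cop_roc"))
  cv <- roc$curve
  j <- cv$sensitivity + cv$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.min(cv$threshold[best])]
  cutoff <- cv$threshold[pick]
  if (max(j) <= 0) {
    warning("Youden J is not positive: the marker does not separate the groups",
            call. = FALSE)
  }
  pos <- roc$scores >= cutoff
  tp <- sum(pos & roc$labels); fp <- sum(pos & !roc$labels)
  fn <- sum(!pos & roc$labels); tn <- sum(!pos & !roc$labels)
  structure(
    c(list(cutoff = cutoff, youden_j = max(j),
           tp = tp, fp = fp, tn = tn, fn = fn),
      confusion_stats(tp, fp, tn, fn)),
    class = "cop_cutoff")
}

#' @export
print.cop_cutoff <- function(x, ...) {
  cat(sprintf(paste0("<cop_cutoff> cutoff = %.4g (J = %.3f)\n",
                     "  sens %.3f  spec %.3f  ppv %.3f  npv %.3f",
                     "  (tp %d fp %d tn %d fn %d)\n"),
              x$cutoff, x$youden_j, x$sensitivity, x$specificity,
              x$ppv, x$npv, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Diagnostic rates from a 2x2 confusion table
#'
#' @param tp,fp,tn,fn Non-negative integer counts; at least one subject with
#'   and one without the condition are required.
#' @return List with `sensitivity` (tp/(tp+fn)), `specificity` (tn/(tn+fp)),
#'   `ppv` (tp/(tp+fp)) and `npv` (tn/(tn+fn)); a ratio with a zero
#'   denominator is reported as `NA`, never as 0.
#' @export
confusion_stats <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("all-zero confusion table", call. = FALSE)
  if (tp + fn == 0 || tn + fp == 0) {
    stop("need at least one subject in each true class", call. = FALSE)
  }
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  list(sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       ppv = ratio(tp, tp + fp),
       npv = ratio(tn, tn + fn))
}

#' Dichotomize a marker at a cut-off
#'
#' Inclusive convention: a value equal to the cut-off is positive.
#'
#' @param scores Numeric marker values.
#' @param cutoff Finite threshold.
#' @return Logical vector `scores >= cutoff`.
#' @export
dichotomize <- function(scores, cutoff) {
  if (!is.finite(cutoff)) stop("`cutoff` must be finite", call. = FALSE)
  scores >= cutoff
}

#' Screen a panel of indexes against the endpoint
#'
#' For every metric column: per-group mean ± SD, the two-group comparison
#' p-value under the automatic test policy, and the AUC with its DeLong
#' confidence interval. Rows are sorted by AUC, descending — the report
#' shape of a full index-screening supplement. Raw p-values are reported
#' (no multiplicity adjustment, matching the screening convention); a
#' Benjamini-Hochberg column can be added as a labelled extension.
#'
#' @param metrics Wide data frame of metric columns (plus optional
#'   `subject_id`, ignored).
#' @param endpoint Binary endpoint vector, one per row.
#' @param adjust Add a `p_adj_bh` Benjamini-Hochberg column (default
#'   `FALSE`).
#' @return Data frame with columns `index`, `mean_without`, `sd_without`,
#'   `mean_with`, `sd_with`, `test`, `p_value`, `auc`, `auc_lo`, `auc_hi`
#'   (and optionally `p_adj_bh`).
#' @export
screen_indexes <- function(metrics, endpoint, adjust = FALSE) {
  endpoint <- as_binary(endpoint, "endpoint")
  cols <- setdiff(names(metrics), "subject_id")
  rows <- lapply(cols, function(nm) {
    x <- metrics[[nm]]
    if (all(is.na(x)) || stats::sd(x, na.rm = TRUE) == 0) {
      return(data.frame(index = nm, mean_without = mean(x[!endpoint]),
                        sd_without = 0, mean_with = mean(x[endpoint]),
                        sd_with = 0, test = NA_character_,
                        p_value = NA_real_, auc = 0.5,
                        auc_lo = NA_real_, auc_hi = NA_real_))
    }
    cmp <- compare_groups(x, endpoint)
    roc <- suppressWarnings(roc_curve(x, endpoint))
    ci <- suppressWarnings(auc_ci(roc))
    data.frame(index = nm,
               mean_without = mean(x[!endpoint]), sd_without = stats::sd(x[!endpoint]),
               mean_with = mean(x[endpoint]), sd_with = stats::sd(x[endpoint]),
               test = cmp$test, p_value = cmp$p_value,
               auc = roc$auc, auc_lo = ci[1], auc_hi = ci[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj_bh <- stats::p.adjust(out$p_value, "BH")
  out[order(-out$auc), , drop = FALSE]
}
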