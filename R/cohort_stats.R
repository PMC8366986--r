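#' Per-group descriptive summary of one variable
#'
#' Continuous variables are summarized as mean and SD, dichotomous ones as
#' count and percentage, per endpoint group and overall.
#'
#' @param x Numeric vector, or logical/factor/character flag vector.
#' @param by Binary endpoint (logical or two-level factor) of the same
#'   length.
#' @return A data frame with one row per stratum (`overall`, then one per
#'   group) and columns `stratum`, `n`, and either `mean`/`sd` or
#'   `count`/`percent`.
#' @export
describe <- function(x, by) {
  by <- as_binary(by, "by")
  if (length(x) != length(by)) stop("`x` and `by` lengths differ", call. = FALSE)
  strata <- list(overall = rep(TRUE, length(x)),
                 `FALSE` = !by, `TRUE` = by)
  for (nm in c("FALSE", "TRUE")) {
    if (!any(strata[[nm]])) stop("empty group: ", nm, call. = FALSE)
  }
  numeric_x <- is.numeric(x)
  rows <- lapply(names(strata), function(nm) {
    xi <- x[strata[[nm]]]
    if (numeric_x) {
      data.frame(stratum = nm, n = length(xi), mean = mean(xi),
                 sd = if (length(xi) > 1) stats::sd(xi) else 0)
    } else {
      f <- as_binary(x, "x")[strata[[nm]]]
      data.frame(stratum = nm, n = length(xi), count = sum(f),
                 percent = 100 * mean(f))
    }
  })
  do.call(rbind, rows)
}

as_binary <- function(x, what) {
  if (is.logical(x)) return(x)
  if (is.numeric(x) && all(x %in% c(0, 1))) return(x == 1)
  u <- sort(unique(as.character(x)))
  if (length(u) > 2) stop("`", what, "` must be binary", call. = FALSE)
  # second level (alphabetically) is the positive one: "woman" > "man",
  # TRUE > FALSE; callers compare proportions so orientation only needs to
  # be consistent
  as.character(x) == u[length(u)]
}

#' Two-group comparison of one variable
#'
#' Implements the screening test policy: Welch's t-test for continuous
#' variables that pass a Shapiro-Wilk normality check in both groups at
#' alpha = 0.05, a Mann-Whitney (Wilcoxon rank-sum, normal approximation
#' with tie correction) test otherwise, and a chi-square test without
#' continuity correction for dichotomous variables. The choice is recorded
#' in the result so report tables can state which test produced each
#' p-value.
#'
#' @param x Variable (numeric, or flag for chi-square).
#' @param by Binary endpoint.
#' @param test `"auto"` (policy above) or one of `"t"`, `"mann_whitney"`,
#'   `"chi2"`.
#' @param correct Continuity correction for the chi-square test (default
#'   `FALSE`, matching standard epidemiological practice on large tables).
#' @return A list of class `group_comparison`: `test`, `statistic`,
#'   `p_value`, and the [describe()] summary.
#' @export
compare_groups <- function(x, by, test = c("auto", "t", "mann_whitney", "chi2"),
                           correct = FALSE) {
  test <- match.arg(test)
  by <- as_binary(by, "by")
  if (!any(by) || !any(!by)) {
    stop("both endpoint groups must be non-empty", call. = FALSE)
  }
  categorical <- !is.numeric(x) || all(x %in% c(0, 1))
  if (test == "auto") {
    test <- if (categorical) "chi2" else {
      normal_both <- tryCatch({
        ps <- vapply(split(x, by), function(g) {
          if (length(g) < 3 || stats::sd(g) == 0) return(0)
          stats::shapiro.test(g[seq_len(min(length(g), 5000))])$p.value
        }, numeric(1))
        all(ps > 0.05)
      }, error = function(e) FALSE)
      if (normal_both) "t" else "mann_whitney"
    }
  }
  res <- switch(test,
    t = {
      h <- stats::t.test(x[by], x[!by])
      list(statistic = unname(h$statistic), p_value = h$p.value)
    },
    mann_whitney = {
      h <- suppressWarnings(stats::wilcox.test(x[by], x[!by], exact = FALSE))
      list(statistic = unname(h$statistic), p_value = h$p.value)
    },
    chi2 = {
      f <- as_binary(x, "x")
      tab <- table(factor(f, c(FALSE, TRUE)), factor(by, c(FALSE, TRUE)))
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
        stop("degenerate 2x2 table: a margin is zero", call. = FALSE)
      }
      h <- suppressWarnings(stats::chisq.test(tab, correct = correct))
      list(statistic = unname(h$statistic), p_value = h$p.value)
    })
  structure(
    list(test = test, statistic = res$statistic, p_value = res$p_value,
         summary = describe(x, by)),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> test = %s, statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Descriptive characteristics table by endpoint group
#'
#' Builds a "Table 1"-style summary: one row per variable with overall and
#' per-group summaries (mean ± SD or n (%)) and the two-group comparison
#' p-value under the automatic test policy of [compare_groups()].
#'
#' @param data A data frame (e.g. a [generate_cohort()] table).
#' @param vars Character vector of column names to summarize.
#' @param by Name of the binary endpoint column (default
#'   `"balance_alteration"`).
#' @return A data frame with columns `variable`, `overall`, `without`,
#'   `with`, `test`, `p_value`.
#' @export
table_one <- function(data, vars, by = "balance_alteration") {
  rows <- lapply(vars, function(v) {
    cmp <- compare_groups(data[[v]], data[[by]])
    s <- cmp$summary
    fmt <- function(row) {
      if ("mean" %in% names(s)) sprintf("%.2f ± %.2f", row$mean, row$sd)
      else sprintf("%d (%.1f)", row$count, row$percent)
    }
    data.frame(variable = v,
               overall = fmt(s[s$stratum == "overall", ]),
               without = fmt(s[s$stratum == "FALSE", ]),
               with = fmt(s[s$stratum == "TRUE", ]),
               test = cmp$test,
               p_value = cmp$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
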