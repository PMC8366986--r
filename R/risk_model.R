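#' Fit the adjusted logistic risk model
#'
#' Maximum-likelihood logistic regression of the balance-alteration
#' endpoint on the dichotomized velocity index adjusted for sex, age and
#' BMI (or any covariate list), fitted by iteratively reweighted least
#' squares via [stats::glm()]. Inference is Wald: standard errors and
#' two-sided p-values on the coefficients, odds ratios `OR = exp(beta)`
#' with confidence intervals obtained by exponentiating the Wald limits.
#' Rows with any missing model variable are dropped (complete-case), with
#' the count recorded. The fit carries its own apparent-performance
#' summaries: ROC/AUC of the fitted probabilities ([model_auc()]) and the
#' Hosmer-Lemeshow calibration test.
#'
#' @param data Data frame holding the covariates and endpoint.
#' @param covariates Character vector of covariate column names; the
#'   default matches the adjusted model (dichotomized AP mean velocity,
#'   sex with woman = 1, age in years, BMI in kg/m^2). Factor-free numeric
#'   or logical columns are expected.
#' @param endpoint Name of the binary endpoint column.
#' @param level Confidence level for the Wald intervals (default 0.95).
#' @param hl_groups Number of Hosmer-Lemeshow risk groups (default 10).
#' @return An object of class `logistic_fit`: `coefficients` (a data frame
#'   with `term`, `beta`, `se`, `z`, `p_value`, `or`, `or_lo`, `or_hi`),
#'   `fitted`, `endpoint`, `auc`, `auc_ci`, `hosmer_lemeshow`, `n_used`,
#'   `n_dropped`, `converged`.
#' @export
fit_logistic <- function(data,
                         covariates = c("mvelap_dic", "sex_woman", "age", "bmi"),
                         endpoint = "balance_alteration",
                         level = 0.95, hl_groups = 10) {
  missing_cols <- setdiff(c(covariates, endpoint), names(data))
  if (length(missing_cols)) {
    stop("columns not found in `data`: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  mf <- data[, c(endpoint, covariates)]
  mf[] <- lapply(mf, function(col) as.numeric(as_binary_or_numeric(col)))
  cc <- stats::complete.cases(mf)
  n_dropped <- sum(!cc)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) dropped for missing model variables (complete-case)")
  }
  mf <- mf[cc, ]
  y <- mf[[endpoint]]
  if (length(unique(y)) < 2) {
    stop("endpoint must have both classes after complete-case filtering",
         call. = FALSE)
  }
  fml <- stats::as.formula(
    paste(endpoint, "~", paste(covariates, collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = mf,
               control = stats::glm.control(epsilon = 1e-10, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (separation || !fit$converged) {
    sm <- summary(fit)$coefficients
    worst <- rownames(sm)[-1][which.max(abs(sm[-1, "Estimate"]))]
    stop("logistic fit did not converge (possible complete separation, ",
         "largest coefficient on `", worst, "`)", call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - level) / 2)
  beta <- sm[, "Estimate"]; se <- sm[, "Std. Error"]
  coefs <- data.frame(
    term = c("constant", covariates),
    beta = unname(beta), se = unname(se),
    z = unname(beta / se),
    p_value = unname(2 * stats::pnorm(-abs(beta / se))),
    or = unname(exp(beta)),
    or_lo = unname(exp(beta - z * se)),
    or_hi = unname(exp(beta + z * se)),
    stringsAsFactors = FALSE)
  p_hat <- stats::fitted(fit)
  roc <- roc_curve(p_hat, y)
  structure(
    list(coefficients = coefs, fitted = unname(p_hat), endpoint = y,
         auc = roc$auc, auc_ci = suppressWarnings(auc_ci(roc)),
         hosmer_lemeshow = hosmer_lemeshow(p_hat, y, g = hl_groups),
         n_used = nrow(mf), n_dropped = n_dropped,
         converged = fit$converged, level = level),
    class = "logistic_fit")
}

as_binary_or_numeric <- function(col) {
  if (is.numeric(col)) col else as_binary(col, "covariate")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic risk model (n = %d%s)\n", x$n_used,
              if (x$n_dropped) sprintf(", %d dropped", x$n_dropped) else ""))
  tab <- x$coefficients
  cat(sprintf("  %-14s %6s %6s %8s   %s\n", "term", "OR", "beta", "p", "95% CI"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("  %-14s %6.2f %6.2f %8s   %.2f-%.2f\n",
                tab$term[i], tab$or[i], tab$beta[i],
                ifelse(tab$p_value[i] < 0.001, "<0.001",
                       sprintf("%.3f", tab$p_value[i])),
                tab$or_lo[i], tab$or_hi[i]))
  }
  hl <- x$hosmer_lemeshow
  cat(sprintf("  Hosmer-Lemeshow chi2 = %.3f, df = %d, p = %.3f\n",
              hl$chi2, hl$df, hl$p_value))
  cat(sprintf("  Area under ROC curve: %.3f\n", x$auc))
  invisible(x)
}

#' Predict the probability of a balance alteration
#'
#' The risk-equation prediction
#' \deqn{P = \frac{1}{1 + e^{-(\beta_0 + \beta_1 X_1 + \beta_2 X_2 +
#'   \beta_3 X_3 + \beta_4 X_4)}}}
#' with `X_1` the dichotomized AP mean velocity (1 when at or above the
#' cut-off), `X_2` sex coded woman = 1, `X_3` age in years and `X_4` BMI in
#' kg/m^2. `object` may be a fitted [fit_logistic()] model or a bare
#' coefficient vector in that order, e.g. the published coefficients.
#'
#' @param object A `logistic_fit` or numeric coefficient vector
#'   `(constant, velocity_dic, sex_woman, age, bmi)`.
#' @param mvelap_dic 0/1 (or the result of [dichotomize()]).
#' @param sex_woman 0/1, woman = 1.
#' @param age Age in years.
#' @param bmi Body-mass index in kg/m^2.
#' @return Probability in (0, 1); vectorized over the covariates.
#' @export
predict_probability <- function(object, mvelap_dic, sex_woman, age, bmi) {
  beta <- if (inherits(object, "logistic_fit")) object$coefficients$beta
          else as.numeric(object)
  if (length(beta) != 5) {
    stop("expected 5 coefficients (constant, velocity_dic, sex_woman, age, bmi)",
         call. = FALSE)
  }
  lp <- beta[1] + beta[2] * as.numeric(mvelap_dic) +
    beta[3] * as.numeric(sex_woman) + beta[4] * age + beta[5] * bmi
  stats::plogis(lp)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Subjects are ranked by fitted probability and split into `g`
#' near-equal-count risk groups (quantile breaks; tied probabilities stay
#' together, so fewer than `g` groups can result). The statistic sums
#' `(observed - expected)^2 / expected` over both outcomes in every group
#' and is referred to chi-square with `df = groups - 2`.
#'
#' @param p Fitted probabilities.
#' @param y Binary outcomes.
#' @param g Number of risk groups (default 10, giving df = 8).
#' @return List of class `hl_test`: `chi2`, `df`, `p_value`, `groups`, and
#'   the per-group `table` (n, observed, expected).
#' @export
hosmer_lemeshow <- function(p, y, g = 10) {
  y <- as.numeric(as_binary(y, "y"))
  if (length(p) != length(y)) stop("`p` and `y` lengths differ", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("`p` must be probabilities", call. = FALSE)
  breaks <- unique(stats::quantile(p, probs = seq(0, 1, length.out = g + 1)))
  if (length(breaks) < 3) {
    stop("fitted probabilities too concentrated to form risk groups; ",
         "reduce `g`", call. = FALSE)
  }
  grp <- cut(p, breaks, include.lowest = TRUE)
  n_g <- as.vector(table(grp))
  o1 <- as.vector(tapply(y, grp, sum))
  e1 <- as.vector(tapply(p, grp, sum))
  e0 <- n_g - e1
  if (any(e1 <= 0) || any(e0 <= 0)) {
    stop("a risk group has zero expected count; use a smaller `g`",
         call. = FALSE)
  }
  chi2 <- sum((o1 - e1)^2 / e1 + ((n_g - o1) - e0)^2 / e0)
  df <- nlevels(grp) - 2L
  structure(
    list(chi2 = chi2, df = df,
         p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
         groups = nlevels(grp),
         table = data.frame(n = n_g, observed = o1, expected = e1)),
    class = "hl_test")
}

#' @export
print.hl_test <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: chi2 = %.3f, df = %d, p = %.3f (%d groups)\n",
              x$chi2, x$df, x$p_value, x$groups))
  invisible(x)
}

#' Cochran sample size for estimating a proportion
#'
#' The large-population formula \eqn{n = z^2 p q / d^2} with `q = 1 - p`,
#' `z` the two-sided normal quantile of the confidence level and `d` the
#' desired absolute precision; the required size is rounded up.
#'
#' @param p Anticipated population proportion, in (0, 1).
#' @param d Desired absolute precision, in (0, 1).
#' @param confidence Confidence level (default 0.95, z = 1.96).
#' @return List of class `sample_size`: `z`, `p`, `q`, `d`, `n_exact`,
#'   `n_required`.
#' @export
cochran_sample_size <- function(p, d, confidence = 0.95) {
  if (!is.numeric(p) || p <= 0 || p >= 1) stop("`p` must be in (0, 1)", call. = FALSE)
  if (!is.numeric(d) || d <= 0 || d >= 1) stop("`d` must be in (0, 1)", call. = FALSE)
  if (confidence <= 0 || confidence >= 1) stop("`confidence` must be in (0, 1)", call. = FALSE)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  n <- z^2 * p * (1 - p) / d^2
  structure(list(z = z, p = p, q = 1 - p, d = d,
                 n_exact = n, n_required = ceiling(n)),
            class = "sample_size")
}

#' @export
print.sample_size <- function(x, ...) {
  cat(sprintf("Cochran sample size: n = %.2f -> %d (z = %.3f, p = %g, d = %g)\n",
              x$n_exact, x$n_required, x$z, x$p, x$d))
  invisible(x)
}

#' ROC of a fitted risk model on its own data
#'
#' @param fit A [fit_logistic()] result.
#' @return A [roc_curve()] of the fitted probabilities against the
#'   endpoint.
#' @export
model_auc <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  roc_curve(fit$fitted, fit$endpoint)
}
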