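#' Configuration for the synthetic study generator
#'
#' Defaults reproduce the printed structure of the reference cohort of 414
#' community-dwelling adults aged 60+ (115 with a balance alteration, 299
#' without): per-group covariate means/SDs, identical 72.2% proportion of
#' women in both groups, per-group mean-velocity targets for the sway
#' trajectories, and the generating logistic coefficients
#' (constant, dichotomized AP mean velocity, sex(women), age, BMI) =
#' (-17.32, 1.08, 0.23, 0.16, 0.16).
#'
#' Velocity targets default to moment-matched lognormal draws (velocities
#' are positive and right-skewed); a truncated-normal option is kept for
#' analytic checks. The four per-subject velocity targets (AP/ML x OE/CE)
#' share a latent sway-severity factor through a Gaussian copula
#' (`velocity_correlation`), reflecting that a subject's sway magnitudes
#' are correlated across axes and eye conditions; this also keeps the
#' open-eyes AP velocity the best-discriminating index, as in the reference
#' cohort where every closed-eyes index ranks below the top open-eyes ones.
#' Gait speed is stored in cm/s (its printed "m/s" values are only
#' plausible as cm/s). Other covariates are generated independently within
#' group; between-covariate correlations are not emulated.
#'
#' @param n_subjects Cohort size (default 414).
#' @param prevalence Proportion with a balance alteration (default 115/414).
#' @param endpoint_mode `"A"`: group membership fixed by sampling, matching
#'   the printed group sizes (default, reproduces the printed tables);
#'   `"B"`: endpoint drawn from the generating logistic model given the
#'   covariates and the dichotomized velocity, enabling parameter-recovery
#'   experiments.
#' @param velocity_family `"lognormal"` (default) or `"normal"` for the
#'   per-subject velocity targets.
#' @param beta Generating logistic coefficients, in the order constant,
#'   dichotomized AP velocity, sex (woman = 1), age, BMI.
#' @param cutoff Velocity dichotomization threshold used by endpoint mode B
#'   (mm/s).
#' @param p_women Proportion of women in both groups.
#' @param covariates,flags,velocity Per-group distribution parameters; each
#'   entry is `c(without, with)` for the balance-alteration groups
#'   (means/SDs for continuous covariates, proportions for flags).
#' @param velocity_correlation Latent-factor loading of the Gaussian copula
#'   tying the four velocity targets together (default 0.8, i.e. pairwise
#'   rank correlation about 0.64); 0 makes them independent.
#' @param duration,sample_rate Trajectory length (s) and sampling rate (Hz).
#' @param seed Integer seed; every generator draw is reproducible given it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 414,
                             prevalence = 115 / 414,
                             endpoint_mode = c("A", "B"),
                             velocity_family = c("lognormal", "normal"),
                             beta = c(constant = -17.32, mvelap_dic = 1.08,
                                      sex_woman = 0.23, age = 0.16, bmi = 0.16),
                             cutoff = 14.24,
                             p_women = 0.722,
                             covariates = list(
                               age        = list(mean = c(68.49, 74.73), sd = c(6.07, 6.10), min = 60, max = 105),
                               bmi        = list(mean = c(26.95, 29.15), sd = c(3.92, 4.86), min = 10, max = 70),
                               gait_speed = list(mean = c(108.22, 92.93), sd = c(23.73, 24.95), min = 5, max = 250),
                               squats     = list(mean = c(10.35, 8.77),  sd = c(2.88, 2.88), min = 0, max = 40)),
                             flags = list(
                               multimorbidity  = c(0.237, 0.417),
                               polypharmacy    = c(0.351, 0.548),
                               falls_last_year = c(0.388, 0.409)),
                             velocity = list(
                               mvelap_oe = list(mean = c(10.88, 15.35), sd = c(4.43, 7.06)),
                               mvelml_oe = list(mean = c(11.00, 13.20), sd = c(4.50, 6.00)),
                               mvelap_ce = list(mean = c(17.43, 22.47), sd = c(9.69, 12.56)),
                               mvelml_ce = list(mean = c(14.00, 17.00), sd = c(7.00, 9.00))),
                             velocity_correlation = 0.8,
                             duration = 60, sample_rate = 50,
                             seed = 1L) {
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop("config error: `prevalence` must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  if (n_subjects < 2) stop("config error: need at least 2 subjects", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects), prevalence = prevalence,
         endpoint_mode = match.arg(endpoint_mode),
         velocity_family = match.arg(velocity_family),
         beta = beta, cutoff = cutoff, p_women = p_women,
         covariates = covariates, flags = flags, velocity = velocity,
         velocity_correlation = velocity_correlation,
         duration = duration, sample_rate = sample_rate,
         seed = as.integer(seed)),
    class = "generator_config")
}

# inverse-CDF truncated normal draw (deterministic under the RNG stream)
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# positive right-skewed quantile function matching a target mean/SD
qvelocity <- function(u, mean, sd, family) {
  if (family == "lognormal") {
    s2 <- log(1 + (sd / mean)^2)
    stats::qlnorm(u, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
  } else {
    p0 <- stats::pnorm(0, mean, sd)  # truncate at 0
    stats::qnorm(p0 + u * (1 - p0), mean, sd)
  }
}

#' Generate a synthetic cohort table
#'
#' Draws one row per subject: demographics, clinical flags, physical
#' performance, the per-condition mean-velocity targets that
#' [generate_trajectory()] later reproduces exactly, and the
#' balance-alteration endpoint. In mode A the group sizes are fixed by
#' `round(n * prevalence)` and covariates are drawn from the per-group
#' distributions; in mode B the endpoint is drawn from the generating
#' logistic model, so downstream model fits can be checked for parameter
#' recovery.
#'
#' @param config A [generator_config()].
#' @return A data frame of class `cohort_table` with columns `subject_id`,
#'   `age`, `sex`, `bmi`, `multimorbidity`, `polypharmacy`,
#'   `falls_last_year`, `gait_speed` (cm/s), `squats`, the four velocity
#'   targets (`mvelap_oe`, `mvelml_oe`, `mvelap_ce`, `mvelml_ce`, mm/s) and
#'   logical `balance_alteration`.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  n1 <- round(n * config$prevalence)
  if (n1 < 1 || n1 > n - 1) {
    stop("config error: prevalence leaves an empty group", call. = FALSE)
  }
  group <- rep(c(0L, 1L), c(n - n1, n1))

  draw_cov <- function(p) {
    rtruncnorm(n, p$mean[group + 1], p$sd[group + 1], p$min, p$max)
  }
  cov_draws <- lapply(config$covariates, draw_cov)
  flag_draws <- lapply(config$flags, function(p) {
    stats::runif(n) < p[group + 1]
  })
  rho <- config$velocity_correlation
  z_severity <- stats::rnorm(n)
  vel_draws <- lapply(config$velocity, function(p) {
    z <- rho * z_severity + sqrt(1 - rho^2) * stats::rnorm(n)
    qvelocity(stats::pnorm(z), p$mean[group + 1], p$sd[group + 1],
              config$velocity_family)
  })
  sex <- ifelse(stats::runif(n) < config$p_women, "woman", "man")

  d <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = cov_draws$age,
    sex = sex,
    bmi = cov_draws$bmi,
    multimorbidity = flag_draws$multimorbidity,
    polypharmacy = flag_draws$polypharmacy,
    falls_last_year = flag_draws$falls_last_year,
    gait_speed = cov_draws$gait_speed,
    squats = pmax(0L, as.integer(round(cov_draws$squats))),
    mvelap_oe = vel_draws$mvelap_oe,
    mvelml_oe = vel_draws$mvelml_oe,
    mvelap_ce = vel_draws$mvelap_ce,
    mvelml_ce = vel_draws$mvelml_ce,
    stringsAsFactors = FALSE)

  if (config$endpoint_mode == "A") {
    d$balance_alteration <- group == 1L
  } else {
    lp <- config$beta[1] +
      config$beta[2] * as.numeric(d$mvelap_oe >= config$cutoff) +
      config$beta[3] * as.numeric(d$sex == "woman") +
      config$beta[4] * d$age +
      config$beta[5] * d$bmi
    d$balance_alteration <- stats::runif(n) < stats::plogis(lp)
  }
  class(d) <- c("cohort_table", "data.frame")
  d
}

#' Generate a sway-like CoP trajectory with an exact mean-velocity target
#'
#' Simulates a band-limited random sway trace: Gaussian displacement
#' increments low-pass filtered below `lowpass_hz` (zero-phase 2nd-order
#' Butterworth), then each axis' increments are rescaled so that the
#' computed axis mean velocity (`sum(|diff|) / T`) equals the requested
#' target exactly — the rescaling is exact for this metric, all other
#' measures are emergent. A target of 0 yields a constant trace. No
#' quantization is applied, so the velocity round-trip holds to machine
#' precision.
#'
#' @param mvel_ap_target,mvel_ml_target Axis mean-velocity targets (mm/s),
#'   `>= 0`.
#' @param duration Record length (s, default 60).
#' @param rate Sampling rate (Hz, default 50).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (so whole-study generation stays reproducible from one seed).
#' @param lowpass_hz Increment low-pass corner (Hz, default 5, the upper
#'   edge of the posturographic analysis band).
#' @param subject_id,condition Passed to [cop_recording()].
#' @return A [cop_recording()].
#' @export
generate_trajectory <- function(mvel_ap_target, mvel_ml_target,
                                duration = 60, rate = 50, seed = NULL,
                                lowpass_hz = 5,
                                subject_id = NA_character_, condition = "OE") {
  if (mvel_ap_target < 0 || mvel_ml_target < 0) {
    stop("velocity targets must be >= 0", call. = FALSE)
  }
  n <- round(duration * rate)
  if (n < 16) stop("duration * rate must give at least 16 samples", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  T_rec <- (n - 1) / rate

  axis <- function(target) {
    if (target == 0) return(numeric(n))
    inc <- stats::rnorm(n - 1)
    if (lowpass_hz < rate / 2) {
      bf <- signal::butter(2, lowpass_hz / (rate / 2), type = "low")
      inc <- signal::filtfilt(bf, inc)
    }
    inc <- inc * (target * T_rec / sum(abs(inc)))
    cumsum(c(0, inc))
  }
  cop_recording(ml = axis(mvel_ml_target), ap = axis(mvel_ap_target),
                sample_rate = rate, subject_id = subject_id,
                condition = condition)
}

#' Compute the full metric table for a synthetic cohort
#'
#' Generates both eye-condition trajectories for every cohort row (targets
#' taken from the cohort's velocity columns, RNG continuing from the current
#' stream) and assembles the wide 78-column metric table.
#'
#' @param cohort A `cohort_table` from [generate_cohort()].
#' @param config The [generator_config()] used (for duration/rate).
#' @return A data frame: `subject_id` plus 78 metric columns.
#' @export
compute_study_metrics <- function(cohort, config = generator_config()) {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    oe <- generate_trajectory(cohort$mvelap_oe[i], cohort$mvelml_oe[i],
                              duration = config$duration,
                              rate = config$sample_rate,
                              subject_id = cohort$subject_id[i],
                              condition = "OE")
    ce <- generate_trajectory(cohort$mvelap_ce[i], cohort$mvelml_ce[i],
                              duration = config$duration,
                              rate = config$sample_rate,
                              subject_id = cohort$subject_id[i],
                              condition = "CE")
    compute_all_metrics(oe, ce)
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(subject_id = cohort$subject_id, out, stringsAsFactors = FALSE)
}

#' Materialize a synthetic study directory
#'
#' Writes `cohort.csv` plus one recording CSV per subject and condition
#' (`recordings/<subject>_<OE|CE>.csv`) in the package's recording-file
#' dialect, so the whole analysis can be re-run from files.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
generate_study_files <- function(config = generator_config(), dir) {
  cohort <- generate_cohort(config)
  rec_dir <- file.path(dir, "recordings")
  dir.create(rec_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  for (i in seq_len(nrow(cohort))) {
    for (cond in c("OE", "CE")) {
      tgt <- if (cond == "OE") c(cohort$mvelap_oe[i], cohort$mvelml_oe[i])
             else c(cohort$mvelap_ce[i], cohort$mvelml_ce[i])
      rec <- generate_trajectory(tgt[1], tgt[2], duration = config$duration,
                                 rate = config$sample_rate,
                                 subject_id = cohort$subject_id[i],
                                 condition = cond)
      write_cop_recording(
        rec, file.path(rec_dir, sprintf("%s_%s.csv", cohort$subject_id[i], cond)))
    }
  }
  invisible(dir)
}
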