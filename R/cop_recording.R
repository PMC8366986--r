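#' Construct a center-of-pressure recording
#'
#' A `cop_recording` holds one subject's raw CoP displacement trace for one
#' eye condition: two uniformly sampled channels (medio-lateral and
#' antero-posterior displacement, in mm) plus sample times. The reference
#' acquisition device samples at a stable 50 Hz for one minute per condition
#' with 0.01 mm displacement resolution; shorter records are accepted and
#' flagged via the `full_minute` field.
#'
#' @param ml Medio-lateral displacement series (mm).
#' @param ap Antero-posterior displacement series (mm), same length as `ml`.
#' @param sample_rate Sampling rate in Hz (device constant 50).
#' @param t Optional sample times (s). If omitted, a uniform grid
#'   `(0:(n-1))/sample_rate` is used. Must be strictly increasing and uniform
#'   to within 1e-9 s; irregular traces must go through [resample_uniform()]
#'   first.
#' @param subject_id Opaque subject identifier.
#' @param condition Eye condition, `"OE"` (open) or `"CE"` (closed).
#' @param nominal_duration Nominal record length in s used to flag short
#'   records (default 60).
#'
#' @return An object of class `cop_recording` with fields `subject_id`,
#'   `condition`, `sample_rate`, `t`, `ml`, `ap`, `duration` and
#'   `full_minute`.
#' @seealso [preprocess()], [read_cop_recording()], [generate_trajectory()]
#' @export
cop_recording <- function(ml, ap, sample_rate = 50, t = NULL,
                          subject_id = NA_character_,
                          condition = c("OE", "CE"),
                          nominal_duration = 60) {
  condition <- match.arg(condition)
  ml <- as.numeric(ml)
  ap <- as.numeric(ap)
  if (length(ml) != length(ap)) {
    stop("`ml` and `ap` must have the same length", call. = FALSE)
  }
  n <- length(ml)
  if (n < 2) {
    stop("invalid recording: fewer than 2 samples", call. = FALSE)
  }
  if (!is.finite(sample_rate) || sample_rate <= 0) {
    stop("`sample_rate` must be a positive number", call. = FALSE)
  }
  if (is.null(t)) {
    t <- (seq_len(n) - 1) / sample_rate
  } else {
    t <- as.numeric(t)
    if (length(t) != n) stop("`t` must match the channel length", call. = FALSE)
    dt <- diff(t)
    if (any(dt <= 0)) stop("`t` must be strictly increasing", call. = FALSE)
    if (max(abs(dt - 1 / sample_rate)) > 1e-9) {
      stop("timestamps are not uniform at `sample_rate`; ",
           "resample with resample_uniform() first", call. = FALSE)
    }
  }
  duration <- t[n] - t[1]
  structure(
    list(subject_id = subject_id, condition = condition,
         sample_rate = sample_rate, t = t, ml = ml, ap = ap,
         duration = duration,
         full_minute = duration >= nominal_duration - 1 / sample_rate),
    class = "cop_recording")
}

#' @export
print.cop_recording <- function(x, ...) {
  cat(sprintf("<cop_recording> subject %s, condition %s: %d samples at %g Hz (%.2f s)%s\n",
              x$subject_id, x$condition, length(x$ap), x$sample_rate,
              x$duration, if (x$full_minute) "" else " [short record]"))
  invisible(x)
}

#' Resample an irregularly sampled series onto a uniform grid
#'
#' Linear interpolation onto a uniform grid at `target_rate` spanning
#' `[t[1], t[n]]`. Provided for CoP traces from devices with an unstable
#' sampling clock; the reference device fixes the rate in hardware, so its
#' files never need this.
#'
#' @param t Sample times (s), strictly increasing.
#' @param x Series values at `t`.
#' @param target_rate Target sampling rate (Hz).
#' @return A list with components `t` (uniform grid) and `x` (interpolated
#'   values).
#' @export
resample_uniform <- function(t, x, target_rate) {
  t <- as.numeric(t); x <- as.numeric(x)
  if (length(t) != length(x)) stop("`t` and `x` lengths differ", call. = FALSE)
  if (length(t) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(diff(t) == 0)) stop("duplicate timestamps in `t`", call. = FALSE)
  if (any(diff(t) < 0)) stop("`t` must be strictly increasing", call. = FALSE)
  grid <- t[1] + seq(0, floor((t[length(t)] - t[1]) * target_rate)) / target_rate
  list(t = grid, x = stats::approx(t, x, xout = grid)$y)
}

#' Preprocess a recording into a zero-meaned sway series
#'
#' Removes the mean from both displacement channels (so all downstream sway
#' metrics are invariant to where the subject stood on the platform) and
#' derives the resultant-distance series
#' \eqn{RD_i = \sqrt{AP_i^2 + ML_i^2}}. The record duration follows the
#' inter-sample-span convention `T = (n - 1) / sample_rate`.
#'
#' @param rec A [cop_recording()].
#' @return An object of class `sway_series` with fields `AP`, `ML`, `RD`
#'   (mm), `T` (s), `n` and `sample_rate`.
#' @export
preprocess <- function(rec) {
  stopifnot(inherits(rec, "cop_recording"))
  AP <- rec$ap - mean(rec$ap)
  ML <- rec$ml - mean(rec$ml)
  n <- length(AP)
  structure(
    list(AP = AP, ML = ML, RD = sqrt(AP^2 + ML^2),
         T = (n - 1) / rec$sample_rate, n = n, sample_rate = rec$sample_rate),
    class = "sway_series")
}

#' Read / write CoP recording files
#'
#' Recordings are exchanged as plain CSV with columns `time_s`, `ml_mm`,
#' `ap_mm` and an optional leading comment line
#' `# subject_id=<id> condition=<OE|CE> sample_rate=<Hz>` mirroring the
#' labelled files the acquisition device writes (one file per subject and
#' condition, named `<subject>_<OE|CE>.csv`).
#'
#' @param path File path.
#' @return `read_cop_recording()` returns a [cop_recording()];
#'   `write_cop_recording()` returns `path` invisibly.
#' @export
read_cop_recording <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- list(subject_id = NA_character_, condition = "OE", sample_rate = NA)
  if (startsWith(header, "#")) {
    for (kv in strsplit(trimws(sub("^#", "", header)), "[[:space:]]+")[[1]]) {
      p <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(p) == 2) meta[[p[1]]] <- p[2]
    }
  }
  d <- utils::read.csv(path, comment.char = "#")
  rate <- if (!is.na(meta$sample_rate)) as.numeric(meta$sample_rate) else {
    1 / stats::median(diff(d$time_s))
  }
  cop_recording(ml = d$ml_mm, ap = d$ap_mm, sample_rate = rate, t = d$time_s,
                subject_id = meta$subject_id, condition = meta$condition)
}

#' @rdname read_cop_recording
#' @param rec A [cop_recording()] to write.
#' @param digits Number of decimal places written (default 4; the device
#'   itself resolves 0.01 mm).
#' @export
write_cop_recording <- function(rec, path, digits = 4) {
  stopifnot(inherits(rec, "cop_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# subject_id=%s condition=%s sample_rate=%g",
                     rec$subject_id, rec$condition, rec$sample_rate), con)
  utils::write.csv(
    data.frame(time_s = round(rec$t, 6), ml_mm = round(rec$ml, digits),
               ap_mm = round(rec$ap, digits)),
    con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
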