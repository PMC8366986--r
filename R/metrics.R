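#' Registry of the stabilometric index set
#'
#' The device-computed index set comprises 39 measures per eye condition:
#' time-domain distance measures over the planar trajectory and each axis,
#' sway areas, hybrid (frequency-like and fractal) measures, and spectral
#' measures of each of the AP, ML and resultant-distance series. The
#' registry is the single machine-readable source of the roster; per-subject
#' vectors carry these names suffixed with the condition (`OE`/`CE`), e.g.
#' `MVELAPOE`.
#'
#' @return A data frame with columns `name`, `domain`
#'   (`distance`/`area`/`hybrid`/`frequency`), `direction`
#'   (`planar`/`AP`/`ML`/`RD`) and `units`.
#' @export
cop_metric_registry <- function() {
  dist_units <- c(MDIST = "mm", RDIST = "mm", RANGE = "mm",
                  MVEL = "mm/s", TOTEX = "mm")
  rows <- list()
  for (base in names(dist_units)) {
    for (dir in c("planar", "AP", "ML")) {
      nm <- paste0(base, if (dir == "planar") "" else dir)
      rows[[nm]] <- c(nm, "distance", dir, dist_units[[base]])
    }
  }
  for (nm in c("AREACC", "AREACE")) rows[[nm]] <- c(nm, "area", "planar", "mm^2")
  rows[["AREASW"]] <- c("AREASW", "area", "planar", "mm^2/s")
  for (dir in c("planar", "AP", "ML")) {
    nm <- paste0("MFREQ", if (dir == "planar") "" else dir)
    rows[[nm]] <- c(nm, "hybrid", dir, "Hz")
  }
  for (nm in c("FD", "FDCC", "FDCE")) rows[[nm]] <- c(nm, "hybrid", "planar", "")
  freq_units <- c(POWER = "mm^2", POWER50 = "Hz", POWER95 = "Hz",
                  CFREQ = "Hz", FREQD = "")
  for (dir in c("AP", "ML", "RD")) {
    for (base in names(freq_units)) {
      nm <- paste0(base, dir)
      rows[[nm]] <- c(nm, "frequency", dir, freq_units[[base]])
    }
  }
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("name", "domain", "direction", "units")
  rownames(out) <- NULL
  out
}

#' Time-domain distance measures of a sway series
#'
#' Computes, for the planar trajectory and for each axis `d` in {AP, ML}:
#' mean distance `MDIST = mean(RD)` / `MDISTd = mean(|d|)`; RMS distance
#' `RDIST = sqrt(mean(RD^2))` / `RDISTd = sqrt(mean(d^2))`; range (planar
#' range is the maximum pairwise distance between trajectory points,
#' evaluated on the convex hull); total excursion `TOTEX` (path length) and
#' mean velocity `MVEL = TOTEX / T`.
#'
#' @param s A `sway_series` from [preprocess()].
#' @return Named numeric vector of 15 distance measures (mm, mm/s).
#' @export
distance_measures <- function(s) {
  stopifnot(inherits(s, "sway_series"))
  dAP <- diff(s$AP); dML <- diff(s$ML)
  totex <- sum(sqrt(dAP^2 + dML^2))
  c(MDIST   = mean(s$RD),
    MDISTAP = mean(abs(s$AP)),
    MDISTML = mean(abs(s$ML)),
    RDIST   = sqrt(mean(s$RD^2)),
    RDISTAP = sqrt(mean(s$AP^2)),
    RDISTML = sqrt(mean(s$ML^2)),
    RANGE   = planar_range(s$AP, s$ML),
    RANGEAP = max(s$AP) - min(s$AP),
    RANGEML = max(s$ML) - min(s$ML),
    MVEL    = totex / s$T,
    MVELAP  = sum(abs(dAP)) / s$T,
    MVELML  = sum(abs(dML)) / s$T,
    TOTEX   = totex,
    TOTEXAP = sum(abs(dAP)),
    TOTEXML = sum(abs(dML)))
}

#' Maximum pairwise planar distance via the convex hull
#'
#' The diameter of the sampled statokinesiogram. Only hull vertices can
#' realize the maximum, so the O(n^2) pair scan is restricted to the hull.
#'
#' @param AP,ML Zero-meaned displacement series (mm).
#' @return The largest inter-point distance (mm).
#' @export
planar_range <- function(AP, ML) {
  pts <- cbind(ML, AP)
  h <- grDevices::chull(pts)
  if (length(h) < 2) return(0)
  max(stats::dist(pts[h, , drop = FALSE]))
}

#' Sway-area measures
#'
#' * `AREACC`: area of the 95% confidence circle,
#'   \eqn{\pi (MDIST + z \cdot s_{RD})^2} with `z = 1.645` and `s_RD` the
#'   sample SD of the resultant distance.
#' * `AREACE`: area of the 95% confidence ellipse,
#'   \eqn{2\pi F \sqrt{s_{AP}^2 s_{ML}^2 - s_{APML}^2}} with the large-sample
#'   constant `F = 3.00` (the 0.05 quantile constant of F(2, n-2)) and
#'   `s_APML` the sample covariance.
#' * `AREASW`: sway area swept per unit time,
#'   \eqn{\frac{1}{2T} \sum_i |AP_{i+1} ML_i - AP_i ML_{i+1}|}.
#'
#' A degenerate (constant) series yields zeros rather than an error.
#'
#' @param s A `sway_series`.
#' @param z Normal quantile for the confidence circle (default 1.645).
#' @param f_stat F constant for the confidence ellipse (default 3.00).
#' @param exact_quantiles If `TRUE`, use `qnorm(0.95)` and
#'   `qf(0.95, 2, n - 2)` instead of the fixed large-sample constants.
#' @return Named numeric vector `AREACC`, `AREACE` (mm^2), `AREASW` (mm^2/s).
#' @export
area_measures <- function(s, z = 1.645, f_stat = 3.00, exact_quantiles = FALSE) {
  stopifnot(inherits(s, "sway_series"))
  if (s$n < 3) stop("area measures require at least 3 samples", call. = FALSE)
  if (exact_quantiles) {
    z <- stats::qnorm(0.95)
    f_stat <- stats::qf(0.95, 2, s$n - 2)
  }
  s_rd <- stats::sd(s$RD)
  v_ap <- stats::var(s$AP); v_ml <- stats::var(s$ML)
  c_apml <- stats::cov(s$AP, s$ML)
  disc <- v_ap * v_ml - c_apml^2
  cross <- abs(s$AP[-1] * s$ML[-s$n] - s$AP[-s$n] * s$ML[-1])
  c(AREACC = pi * (mean(s$RD) + z * s_rd)^2,
    AREACE = 2 * pi * f_stat * sqrt(max(disc, 0)),
    AREASW = sum(cross) / (2 * s$T))
}

#' Hybrid sway measures
#'
#' Frequency-like ratios of time-domain measures and planar fractal
#' dimensions:
#' * `MFREQ = MVEL / (2 pi MDIST)`: the rotation frequency a point moving at
#'   the observed mean speed on a circle of radius `MDIST` would have.
#' * `MFREQd = MVELd / (4 sqrt(2) MDISTd)` for each axis (the analogous
#'   frequency of a sinusoid with the observed axis mean speed/distance).
#' * `FD`, `FDCC`, `FDCE`: fractal dimensions
#'   \eqn{\log n / \log(n \, d / TOTEX)} of the planar curve, with the
#'   characteristic diameter `d` taken as the planar range, the confidence
#'   circle diameter \eqn{2(MDIST + 1.645 s_{RD})}, or the area-equivalent
#'   diameter of the 95% confidence ellipse \eqn{\sqrt{4 \, AREACE / \pi}}.
#'
#' All ratios are defined as 0 (with a warning) when their denominator is 0,
#' so degenerate recordings do not inject non-finite values into cohort
#' tables.
#'
#' @param s A `sway_series`.
#' @param dm Distance measures of `s` (computed if missing).
#' @param am Area measures of `s` (computed if missing).
#' @return Named numeric vector `MFREQ`, `MFREQAP`, `MFREQML` (Hz), `FD`,
#'   `FDCC`, `FDCE` (dimensionless).
#' @export
hybrid_measures <- function(s, dm = distance_measures(s), am = area_measures(s)) {
  safe_ratio <- function(num, den, what) {
    if (den <= 0) {
      if (num > 0) warning("degenerate denominator for ", what, "; returning 0",
                           call. = FALSE)
      return(0)
    }
    num / den
  }
  fd <- function(d) {
    if (dm[["TOTEX"]] <= 0 || d <= 0) return(0)
    arg <- s$n * d / dm[["TOTEX"]]
    if (arg <= 1) return(0)  # pathological: path shorter than its diameter scale
    log(s$n) / log(arg)
  }
  c(MFREQ   = safe_ratio(dm[["MVEL"]],   2 * pi * dm[["MDIST"]], "MFREQ"),
    MFREQAP = safe_ratio(dm[["MVELAP"]], 4 * sqrt(2) * dm[["MDISTAP"]], "MFREQAP"),
    MFREQML = safe_ratio(dm[["MVELML"]], 4 * sqrt(2) * dm[["MDISTML"]], "MFREQML"),
    FD   = fd(dm[["RANGE"]]),
    FDCC = fd(2 * (dm[["MDIST"]] + 1.645 * stats::sd(s$RD))),
    FDCE = fd(sqrt(4 * am[["AREACE"]] / pi)))
}

#' Welch power spectral density estimate
#'
#' One-sided PSD by Welch's method: Hann-windowed segments with overlap,
#' linear detrend per segment, periodograms averaged. Scaled as a density,
#' so `sum(psd) * df` integrates to the signal variance (a sinusoid of
#' amplitude A integrates to A^2/2 over its spectral line).
#'
#' @param x Numeric series.
#' @param fs Sampling rate (Hz).
#' @param segment_s Segment length in seconds (default 10).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param detrend Linearly detrend each segment (default `TRUE`).
#' @return List with `freq` (Hz), `psd` (units^2/Hz) and `df` (bin width, Hz).
#' @export
welch_psd <- function(x, fs, segment_s = 10, overlap = 0.5, detrend = TRUE) {
  n <- length(x)
  nseg <- min(floor(segment_s * fs), n)
  if (nseg < 8) stop("record too short for spectral estimation", call. = FALSE)
  if (nseg < floor(segment_s * fs)) {
    warning("record shorter than one PSD segment; using a single segment",
            call. = FALSE)
  }
  nseg <- nseg - nseg %% 2L  # even length keeps the Nyquist bin explicit
  w <- 0.5 * (1 - cos(2 * pi * (0:(nseg - 1)) / (nseg - 1)))
  step <- max(1L, floor(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  half <- nseg %/% 2L
  acc <- numeric(half + 1L)
  idx <- seq_len(nseg)
  for (s0 in starts) {
    seg <- x[s0 + idx - 1L]
    if (detrend) {
      fit <- stats::lm.fit(cbind(1, idx), seg)
      seg <- fit$residuals
    } else {
      seg <- seg - mean(seg)
    }
    X <- stats::fft(seg * w)[seq_len(half + 1L)]
    P <- Mod(X)^2 / (fs * sum(w^2))
    P[2:half] <- 2 * P[2:half]  # fold negative frequencies; DC/Nyquist single
    acc <- acc + P
  }
  list(freq = (0:half) * fs / nseg, psd = acc / length(starts), df = fs / nseg)
}

#' Frequency-domain sway measures
#'
#' For each of the AP, ML and resultant-distance series, estimates the PSD
#' by [welch_psd()] and summarizes it over the posturographic band (default
#' 0.15-5 Hz) through spectral moments
#' \eqn{\mu_k = \sum f^k G(f) \Delta f}:
#' total power `POWER` (\eqn{\mu_0}), the 50% and 95% power frequencies
#' (smallest band frequency at which cumulative power reaches that fraction
#' of \eqn{\mu_0}), the centroidal frequency
#' `CFREQ` (\eqn{\sqrt{\mu_2/\mu_0}}) and the frequency dispersion
#' `FREQD` (\eqn{\sqrt{1 - \mu_1^2/(\mu_0 \mu_2)}}, 0 for a pure line,
#' approaching 1 for wideband sway). A zero-power series reports all four
#' dependent frequencies as 0 by the degenerate-input convention.
#'
#' @param s A `sway_series`.
#' @param band Analysis band in Hz (default `c(0.15, 5)`); upper edge must be
#'   below Nyquist.
#' @param segment_s,overlap,detrend Passed to [welch_psd()].
#' @return Named numeric vector of 15 measures (`POWER*`, `POWER50*`,
#'   `POWER95*`, `CFREQ*`, `FREQD*` for AP/ML/RD).
#' @export
frequency_measures <- function(s, band = c(0.15, 5), segment_s = 10,
                               overlap = 0.5, detrend = TRUE) {
  stopifnot(inherits(s, "sway_series"))
  if (band[2] >= s$sample_rate / 2) {
    stop("band upper edge must be below the Nyquist frequency", call. = FALSE)
  }
  one <- function(x, dir) {
    ps <- welch_psd(x, s$sample_rate, segment_s, overlap, detrend)
    keep <- ps$freq >= band[1] & ps$freq <= band[2]
    f <- ps$freq[keep]; G <- ps$psd[keep]
    mu0 <- sum(G) * ps$df
    out <- c(POWER = mu0, POWER50 = 0, POWER95 = 0, CFREQ = 0, FREQD = 0)
    if (mu0 > 0 && sum(f^2 * G) > 0) {
      cum <- cumsum(G) * ps$df
      mu1 <- sum(f * G) * ps$df
      mu2 <- sum(f^2 * G) * ps$df
      out[["POWER50"]] <- f[which(cum >= 0.5 * mu0)[1]]
      out[["POWER95"]] <- f[which(cum >= 0.95 * mu0)[1]]
      out[["CFREQ"]] <- sqrt(mu2 / mu0)
      out[["FREQD"]] <- sqrt(max(0, 1 - mu1^2 / (mu0 * mu2)))
    }
    names(out) <- paste0(names(out), dir)
    out
  }
  c(one(s$AP, "AP"), one(s$ML, "ML"), one(s$RD, "RD"))
}

#' Compute the full 39-measure index set for one recording
#'
#' @param rec A [cop_recording()] (or an already preprocessed
#'   `sway_series`).
#' @param ... Passed on to [frequency_measures()] (band, segment length).
#' @return Named numeric vector of the 39 registry measures, in registry
#'   order.
#' @export
compute_condition_metrics <- function(rec, ...) {
  s <- if (inherits(rec, "sway_series")) rec else preprocess(rec)
  dm <- distance_measures(s)
  am <- area_measures(s)
  out <- c(dm, am, hybrid_measures(s, dm, am), frequency_measures(s, ...))
  out[cop_metric_registry()$name]
}

#' Compute the 78-entry per-subject metric vector
#'
#' Combines both eye conditions into one named vector with `OE`/`CE`
#' suffixes (`MVELAP` in the open-eyes recording becomes `MVELAPOE`). A
#' missing condition yields `NA` entries for its 39 measures.
#'
#' @param rec_oe Open-eyes [cop_recording()], or `NULL`.
#' @param rec_ce Closed-eyes [cop_recording()], or `NULL`.
#' @param ... Passed on to [compute_condition_metrics()].
#' @return Named numeric vector of length 78.
#' @export
compute_all_metrics <- function(rec_oe = NULL, rec_ce = NULL, ...) {
  reg <- cop_metric_registry()$name
  one <- function(rec, cond) {
    v <- if (is.null(rec)) stats::setNames(rep(NA_real_, length(reg)), reg)
         else compute_condition_metrics(rec, ...)
    stats::setNames(v, paste0(names(v), cond))
  }
  c(one(rec_oe, "OE"), one(rec_ce, "CE"))
}
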