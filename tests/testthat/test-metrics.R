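test_that("the metric registry defines 39 measures per condition, 78 per subject", {
  reg <- cop_metric_registry()
  expect_equal(nrow(reg), 39)
  expect_false(any(duplicated(reg$name)))
  rec <- generate_trajectory(10, 8, duration = 20, seed = 1)
  m <- compute_condition_metrics(rec)
  expect_equal(names(m), reg$name)
  both <- compute_all_metrics(rec, rec)
  expect_equal(length(both), 78)
  # identical recordings in both conditions give identical values
  expect_equal(unname(both[paste0(reg$name, "OE")]),
               unname(both[paste0(reg$name, "CE")]))
  # missing condition is marked, not invented
  half <- compute_all_metrics(rec_oe = rec)
  expect_true(all(is.na(half[paste0(reg$name, "CE")])))
  expect_false(any(is.na(half[paste0(reg$name, "OE")])))
})

test_that("distance measures match hand-computed values", {
  const <- preprocess(cop_recording(ml = rep(2, 50), ap = rep(3, 50)))
  dm <- distance_measures(const)
  expect_equal(unname(dm[c("MDIST", "RDIST", "RANGE", "MVEL")]),
               c(0, 0, 0, 0))

  # total AP excursion 4 mm over T = 0.08 s
  s <- preprocess(cop_recording(ml = rep(0, 5), ap = c(0, 1, 0, -1, 0),
                                sample_rate = 50))
  expect_equal(unname(distance_measures(s)[["MVELAP"]]), 4 / 0.08)

  circ <- preprocess(circle_recording(R = 5, f = 0.5, rate = 50, cycles = 10))
  dm <- distance_measures(circ)
  expect_equal(dm[["MDIST"]], 5, tolerance = 1e-9)
  expect_equal(dm[["MVEL"]], 2 * pi * 5 * 0.5, tolerance = 0.01)
})

test_that("planar range equals the brute-force diameter", {
  set.seed(11)
  for (i in 1:20) {
    s <- preprocess(random_recording(n = sample(10:200, 1)))
    expect_equal(distance_measures(s)[["RANGE"]], range_brute(s$AP, s$ML),
                 tolerance = 1e-12)
  }
})

test_that("area measures match closed-form and shoelace oracles", {
  # orthogonal unit-variance axes: AREA_CE = 2*pi*3.00*1
  k <- sqrt(3) / 2
  s <- preprocess(cop_recording(ml = k * c(1, 1, -1, -1),
                                ap = k * c(1, -1, 1, -1)))
  expect_equal(var(s$AP), 1)
  expect_equal(cov(s$AP, s$ML), 0)
  expect_equal(area_measures(s)[["AREACE"]], 2 * pi * 3, tolerance = 1e-9)

  # closed square loop through (+-1, +-1) traversed in T = 1 s
  sq_ap <- c(1, 1, -1, -1, 1)
  sq_ml <- c(1, -1, -1, 1, 1)
  s <- preprocess(cop_recording(ml = sq_ml, ap = sq_ap, sample_rate = 4))
  expect_equal(s$T, 1)
  expect_equal(area_measures(s)[["AREASW"]],
               shoelace_area(sq_ap, sq_ml) / s$T)
  expect_equal(area_measures(s)[["AREASW"]], 4)

  const <- preprocess(cop_recording(ml = rep(1, 10), ap = rep(2, 10)))
  expect_equal(unname(area_measures(const)), c(0, 0, 0))
})

test_that("sway area equals the shoelace polygon rate on random convex loops", {
  set.seed(5)
  for (i in 1:10) {
    th <- sort(runif(20, 0, 2 * pi))
    r <- runif(1, 1, 4)
    ap <- c(r * cos(th), r * cos(th[1]))
    ml <- c(r * sin(th), r * sin(th[1]))
    s <- preprocess(cop_recording(ml = ml, ap = ap, sample_rate = 10))
    expect_equal(area_measures(s)[["AREASW"]],
                 shoelace_area(ap - mean(ap), ml - mean(ml)) / s$T,
                 tolerance = 1e-9)
  }
})

test_that("hybrid measures satisfy their defining identities", {
  circ <- preprocess(circle_recording(R = 5, f = 0.5))
  dm <- distance_measures(circ)
  hm <- hybrid_measures(circ, dm)
  # rotation frequency recovered from the circle
  expect_equal(hm[["MFREQ"]], 0.5, tolerance = 0.01)
  # identity MFREQ * 2*pi*MDIST = MVEL holds by construction
  expect_equal(hm[["MFREQ"]] * 2 * pi * dm[["MDIST"]], dm[["MVEL"]],
               tolerance = 1e-12)

  # triangle wave: independent recomputation of the defining ratio,
  # converging to sqrt(2) * f
  tri <- preprocess(triangle_recording(a = 5, f = 1))
  mvel_ap <- sum(abs(diff(tri$AP))) / tri$T
  mdist_ap <- mean(abs(tri$AP))
  expect_equal(hybrid_measures(tri)[["MFREQAP"]],
               mvel_ap / (4 * sqrt(2) * mdist_ap), tolerance = 1e-12)
  expect_equal(hybrid_measures(tri)[["MFREQAP"]], sqrt(2) * 1,
               tolerance = 0.02)

  const <- preprocess(cop_recording(ml = rep(0, 20), ap = rep(0, 20)))
  expect_equal(unname(hybrid_measures(const)[c("MFREQ", "MFREQAP", "FD")]),
               c(0, 0, 0))
})

test_that("spectral measures localize a pure line and spread white noise", {
  t <- (0:2999) / 50
  rec <- cop_recording(ml = numeric(3000), ap = 3 * sin(2 * pi * 1 * t),
                       sample_rate = 50)
  fm <- frequency_measures(preprocess(rec))
  expect_equal(fm[["POWERAP"]], 3^2 / 2, tolerance = 0.01)
  expect_equal(fm[["POWER50AP"]], 1, tolerance = 0.1 + 1e-9)
  expect_equal(fm[["POWER95AP"]], 1, tolerance = 0.1 + 1e-9)
  expect_equal(fm[["CFREQAP"]], 1, tolerance = 0.1)
  expect_lt(fm[["FREQDAP"]], 0.1)

  set.seed(3)
  wn <- cop_recording(ml = rnorm(3000), ap = rnorm(3000), sample_rate = 50)
  fm <- frequency_measures(preprocess(wn))
  expect_equal(fm[["POWER50AP"]], (0.15 + 5) / 2, tolerance = 0.25)

  zero <- preprocess(cop_recording(ml = rep(0, 3000), ap = rep(0, 3000)))
  fm <- frequency_measures(zero)
  expect_equal(unname(fm[c("POWERAP", "POWER50AP", "POWER95AP", "CFREQAP")]),
               c(0, 0, 0, 0))
})

test_that("metrics are translation invariant and scale covariant", {
  set.seed(21)
  reg <- cop_metric_registry()
  scale_linear <- reg$name[reg$domain == "distance"]
  scale_quadratic <- c("AREACC", "AREACE", "AREASW",
                       paste0("POWER", c("AP", "ML", "RD")))
  scale_free <- setdiff(reg$name, c(scale_linear, scale_quadratic))
  for (i in 1:5) {
    rec <- random_recording(n = 1500)
    m0 <- compute_condition_metrics(rec)

    shifted <- cop_recording(ml = rec$ml + 17.3, ap = rec$ap - 4.1,
                             sample_rate = rec$sample_rate)
    expect_equal(compute_condition_metrics(shifted), m0, tolerance = 1e-9)

    c_fac <- 2
    scaled <- cop_recording(ml = c_fac * rec$ml, ap = c_fac * rec$ap,
                            sample_rate = rec$sample_rate)
    m2 <- compute_condition_metrics(scaled)
    expect_equal(unname(m2[scale_linear]), unname(c_fac * m0[scale_linear]),
                 tolerance = 1e-9)
    expect_equal(unname(m2[scale_quadratic]),
                 unname(c_fac^2 * m0[scale_quadratic]), tolerance = 1e-9)
    expect_equal(unname(m2[scale_free]), unname(m0[scale_free]),
                 tolerance = 1e-9)
  }
})

test_that("planar path dominates its axis projections and band limits hold", {
  set.seed(31)
  for (i in 1:10) {
    m <- compute_condition_metrics(random_recording(n = 1200))
    expect_gte(m[["MVEL"]], m[["MVELAP"]])
    expect_gte(m[["MVEL"]], m[["MVELML"]])
    for (dir in c("AP", "ML", "RD")) {
      expect_lte(m[[paste0("POWER50", dir)]], m[[paste0("POWER95", dir)]])
      expect_gte(m[[paste0("CFREQ", dir)]], 0.15)
      expect_lte(m[[paste0("CFREQ", dir)]], 5)
      expect_gte(m[[paste0("FREQD", dir)]], 0)
      expect_lte(m[[paste0("FREQD", dir)]], 1)
    }
    expect_true(all(m[cop_metric_registry()$domain != "hybrid"] >= 0))
  }
})

test_that("short records fall back to a single spectral segment with a warning", {
  rec <- generate_trajectory(10, 10, duration = 5, seed = 2)
  w <- capture_warnings(fm <- frequency_measures(preprocess(rec)))
  expect_match(w, "single segment", all = TRUE)
  expect_length(w, 3)  # one per analyzed series (AP, ML, RD)
  expect_true(all(is.finite(fm)))
})
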