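# Independent brute-force oracles and signal constructors used across tests.

# Mann-Whitney pair-counting AUC: ties count one half.
auc_by_pairs <- function(scores, labels) {
  x <- scores[as.logical(labels)]
  y <- scores[!as.logical(labels)]
  wins <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(wins)
}

# O(n^2) planar diameter.
range_brute <- function(AP, ML) {
  n <- length(AP)
  if (n < 2) return(0)
  best <- 0
  for (i in seq_len(n - 1)) {
    d <- sqrt((AP[-seq_len(i)] - AP[i])^2 + (ML[-seq_len(i)] - ML[i])^2)
    best <- max(best, d)
  }
  best
}

# Shoelace polygon area of a closed sampled loop (last point = first).
shoelace_area <- function(x, y) {
  n <- length(x)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

# Recording tracing k full circles of radius R at rotation frequency f.
circle_recording <- function(R = 5, f = 0.5, rate = 50, cycles = 10) {
  n <- cycles * rate / f         # endpoint omitted: channel means are exactly 0
  t <- (0:(n - 1)) / rate
  cop_recording(ml = R * sin(2 * pi * f * t), ap = R * cos(2 * pi * f * t),
                sample_rate = rate)
}

# AP-only triangle wave of amplitude a and frequency f; ML held flat.
triangle_recording <- function(a = 5, f = 1, rate = 50, duration = 60) {
  t <- (0:(duration * rate - 1)) / rate
  phase <- (f * t) %% 1
  ap <- a * (4 * abs(phase - 0.5) - 1)
  cop_recording(ml = numeric(length(t)), ap = ap, sample_rate = rate)
}

random_recording <- function(n = 600, rate = 50) {
  cop_recording(ml = cumsum(rnorm(n, sd = 0.3)) + runif(1, -5, 5),
                ap = cumsum(rnorm(n, sd = 0.3)) + runif(1, -5, 5),
                sample_rate = rate)
}
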