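# Independent oracles used across the suite.

# Direct-sum correlator: brute-force evaluation of the normalized
# correlation estimator at a single lag (in bins) on a pair of traces,
# written as an explicit loop so it shares no code with the package's
# vectorized multi-tau implementation.
direct_correlation <- function(a, b, k) {
  n <- length(a)
  s_xy <- 0; s_x <- 0; s_y <- 0
  m <- n - k
  for (t in seq_len(m)) {
    s_xy <- s_xy + a[t] * b[t + k]
    s_x <- s_x + a[t]
    s_y <- s_y + b[t + k]
  }
  (s_xy / m) / ((s_x / m) * (s_y / m)) - 1
}

# Direct evaluation of the full multi-tau estimator definition (successive
# 2x rebinning, m lags per stage) using the loop correlator above.
direct_multi_tau <- function(a, b, bin_width, m = 16, max_lag = 1) {
  lag <- c(); G <- c()
  width <- bin_width
  stage <- 0
  repeat {
    ks <- if (stage == 0) 1:m else (m / 2 + 1):m
    stop_now <- FALSE
    for (k in ks) {
      if (k * width > max_lag || length(a) - k < 2 * m) { stop_now <- TRUE; break }
      lag <- c(lag, k * width)
      G <- c(G, direct_correlation(a, b, k))
    }
    if (stop_now || length(a) < 4 * m) break
    half <- floor(length(a) / 2)
    a2 <- numeric(half); b2 <- numeric(half)
    for (i in seq_len(half)) {
      a2[i] <- a[2 * i - 1] + a[2 * i]
      b2[i] <- b[2 * i - 1] + b[2 * i]
    }
    a <- a2; b <- b2
    width <- width * 2
    stage <- stage + 1
  }
  data.frame(lag = lag, G = G)
}

# Ideal step counter: a spot's observed step count is the number of its
# bleaching events inside the recording window.
steps_in_window <- function(trace) {
  sum(trace$truth$bleach_frames <= length(trace$intensity) - 2)
}

expect_fraction_close <- function(est, truth, n, label, z = 3.5) {
  se <- sqrt(max(truth * (1 - truth), 1e-12) / n)
  expect_lt(abs(est - truth), z * se + 1e-12, label = label)
}
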