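# short protocol used by fast unit tests: one lap with one activity of each
# type, 88 s total
quick_config <- function() {
  protocol_config(tibble::tibble(
    regime_id = c("W1", "A1", "W2", "A4", "W3"),
    duration_s = c(25, 10, 18, 15, 20)
  ))
}

# deterministic six-channel block -> imu_recording
block_to_recording <- function(block, rate = 100) {
  n <- length(block$acc_cc)
  imu_recording(
    tibble::as_tibble(c(list(time_s = (seq_len(n) - 1) / rate), block)),
    sampling_rate_hz = rate
  )
}

# pure-tone recording: one named channel carries a sinusoid, others zero
tone_recording <- function(freq_hz, duration_s = 10, rate = 100,
                           channel = "acc_ap", amplitude = 1) {
  n <- round(duration_s * rate)
  t <- (seq_len(n) - 1) / rate
  cols <- c(
    list(time_s = t),
    stats::setNames(
      rep(list(numeric(n)), 6),
      c("acc_cc", "acc_ml", "acc_ap", "gyr_cc", "gyr_ml", "gyr_ap")
    )
  )
  cols[[channel]] <- amplitude * sin(2 * pi * freq_hz * t)
  imu_recording(tibble::as_tibble(cols), sampling_rate_hz = rate)
}

# piecewise-constant multivariate frame matrix with known breakpoints
piecewise_signal <- function(n = 120, d = 3, breaks = c(40, 80), jump = 5,
                             noise = 0.1) {
  levels <- matrix(
    rnorm((length(breaks) + 1) * d, sd = jump),
    ncol = d
  )
  bounds <- c(0, breaks, n)
  y <- matrix(0, n, d)
  for (k in seq_len(length(bounds) - 1)) {
    rows <- (bounds[k] + 1):bounds[k + 1]
    y[rows, ] <- matrix(levels[k, ], length(rows), d, byrow = TRUE) +
      matrix(rnorm(length(rows) * d, sd = noise), ncol = d)
  }
  y
}

# naive two-pass segment cost oracle
naive_cost <- function(m, a, b) {
  seg <- m[(a + 1):b, , drop = FALSE]
  mu <- colMeans(seg)
  sum(sweep(seg, 2, mu)^2)
}

# naive O(n^2) unbiased autocorrelation oracle
naive_acf_unbiased <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  raw <- vapply(0:(n - 1), function(k) {
    sum(x[1:(n - k)] * x[(1 + k):n]) / (n - k)
  }, numeric(1))
  raw / raw[1]
}
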