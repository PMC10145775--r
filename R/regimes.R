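#' Slice a recording into regimes at breakpoint times
#'
#' Produces half-open spans `[start_s, end_s)` covering the recording exactly
#' once.
#'
#' @param rec an [imu_recording()].
#' @param breakpoints_s sorted breakpoint times strictly inside the
#'   recording.
#' @return tibble with columns `regime`, `start_s`, `end_s`.
#' @export
slice_regimes <- function(rec, breakpoints_s) {
  t0 <- rec$time_s[1]
  t1 <- t0 + imu_duration(rec)
  if (length(breakpoints_s) > 0 &&
    (any(breakpoints_s <= t0) || any(breakpoints_s >= t1) ||
      any(diff(breakpoints_s) <= 0))) {
    abort("breakpoints must be strictly increasing and interior to the recording")
  }
  bounds <- c(t0, breakpoints_s, t1)
  tibble::tibble(
    regime = seq_len(length(bounds) - 1),
    start_s = bounds[-length(bounds)],
    end_s = bounds[-1]
  )
}

# rows of rec with start_s <= time_s < end_s
regime_samples <- function(rec, start_s, end_s) {
  rec[rec$time_s >= start_s - 1e-9 & rec$time_s < end_s - 1e-9, ]
}

# nearest-rank percentile: the ceil(p * n / 100)-th value of the sorted array
percentile_rank <- function(x, p) {
  n <- length(x)
  sort(x)[max(1L, ceiling(p * n / 100))]
}

# periodogram |FFT|^2 / n over non-negative frequencies
periodogram <- function(x, fs) {
  n <- length(x)
  p <- Mod(fft(x))^2 / n
  k <- 0:(n %/% 2)
  list(freq = k * fs / n, power = p[k + 1])
}

# first and second dominant frequency / power; the second is the largest
# local maximum at least `excl_hz` away from the first (else it degenerates
# to the bin adjacent to F0). DC is excluded.
dominant_freqs <- function(x, fs, excl_hz = 0.2) {
  pg <- periodogram(x, fs)
  freq <- pg$freq[-1]
  pw <- pg$power[-1]
  if (length(pw) == 0 || all(pw == 0)) {
    return(list(f0 = 0, pd0 = 0, f2 = 0, pd2 = 0))
  }
  i0 <- which.max(pw)
  m <- length(pw)
  is_max <- pw >= c(-Inf, pw[-m]) & pw > c(pw[-1], -Inf)
  ok <- is_max & abs(freq - freq[i0]) > excl_hz
  if (any(ok)) {
    i2 <- which(ok)[which.max(pw[ok])]
    list(f0 = freq[i0], pd0 = pw[i0], f2 = freq[i2], pd2 = pw[i2])
  } else {
    list(f0 = freq[i0], pd0 = pw[i0], f2 = 0, pd2 = 0)
  }
}

# the 21 per-channel classification features
channel_features <- function(x, fs) {
  n <- length(x)
  m <- mean(x)
  s <- sd(x)
  dom <- dominant_freqs(x, fs)
  mid <- x[seq.int(floor(n / 6) + 1L, ceiling(5 * n / 6))]
  c(
    mean = m, std = s, var = s^2, min = min(x), max = max(x),
    pd0 = dom$pd0, f0 = dom$f0, pd2 = dom$pd2, f2 = dom$f2,
    cv = if (abs(m) < 1e-12) 0 else s / m,
    p75 = percentile_rank(x, 75), p25 = percentile_rank(x, 25),
    p85 = percentile_rank(x, 85), p15 = percentile_rank(x, 15),
    p95 = percentile_rank(x, 95), p5 = percentile_rank(x, 5),
    p75m = percentile_rank(mid, 75), p25m = percentile_rank(mid, 25),
    p85m = percentile_rank(mid, 85), p15m = percentile_rank(mid, 15),
    rms = sqrt(mean(x^2))
  )
}

#' Classification features of one regime
#'
#' Computes, on the filtered samples of a regime, 21 temporal and spectral
#' features per channel (mean, SD, variance, min, max, power and location of
#' the two dominant periodogram frequencies, coefficient of variation,
#' nearest-rank percentiles 75/25/85/15/95/5, the 75/25/85/15 percentiles of
#' the central two-thirds of the regime, and RMS), plus the first and second
#' autocorrelation peaks of the craniocaudal acceleration (shared with the
#' gait criteria) and the mean acceleration vector magnitude — 129 features.
#'
#' @param rec a filtered [imu_recording()].
#' @param start_s,end_s the regime's half-open span in seconds.
#' @return named numeric vector of features.
#' @export
extract_features <- function(rec, start_s, end_s) {
  fs <- imu_rate(rec)
  seg <- regime_samples(rec, start_s, end_s)
  if (nrow(seg) < fs) {
    abort("regime too short for feature extraction (need >= 1 s)")
  }
  feats <- unlist(lapply(imu_channels(), function(ch) {
    f <- channel_features(seg[[ch]], fs)
    names(f) <- paste0(names(f), "_", ch)
    f
  }))
  acc_cc <- seg$acc_cc
  peaks <- tryCatch(
    {
      cadence <- cadence_estimate(acc_cc, fs)
      pk <- acf_peaks(
        autocorrelation_unbiased(acc_cc), cadence, fs,
        x = acc_cc
      )
      c(p1_acc_cc = pk$p1, p2_acc_cc = pk$p2)
    },
    error = function(e) c(p1_acc_cc = 0, p2_acc_cc = 0)
  )
  vm <- mean(sqrt(seg$acc_cc^2 + seg$acc_ap^2 + seg$acc_ml^2))
  c(feats, peaks, vm_mean = vm)
}

#' Classification features for a table of regimes
#'
#' @param rec a filtered [imu_recording()].
#' @param regimes tibble with `start_s`, `end_s` (e.g. from
#'   [slice_regimes()]).
#' @return `regimes` with one numeric column per feature appended.
#' @export
features_for_regimes <- function(rec, regimes) {
  mat <- t(vapply(
    seq_len(nrow(regimes)),
    function(i) extract_features(rec, regimes$start_s[i], regimes$end_s[i]),
    numeric(129)
  ))
  dplyr::bind_cols(regimes, tibble::as_tibble(mat))
}

feature_columns <- function(df) {
  setdiff(
    names(df)[vapply(df, is.numeric, logical(1))],
    c("regime", "start_s", "end_s")
  )
}
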