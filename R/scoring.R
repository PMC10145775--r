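#' RMS ratios of regime accelerations
#'
#' Per-axis RMS divided by the three-axis RMS magnitude
#' `RMS_A = sqrt(RMS_ML^2 + RMS_CC^2 + RMS_AP^2)`. The mediolateral ratio
#' indexes (in)stability, the anteroposterior ratio sturdiness; the squared
#' ratios sum to one by construction.
#'
#' @param df data frame with columns `acc_cc`, `acc_ml`, `acc_ap` (a regime's
#'   filtered samples).
#' @return one-row tibble with `rmsr_ml`, `rmsr_ap`, `rmsr_cc`.
#' @export
rms_ratios <- function(df) {
  stopifnot(all(c("acc_cc", "acc_ml", "acc_ap") %in% names(df)))
  if (nrow(df) == 0) {
    abort("empty regime")
  }
  rms <- vapply(
    df[c("acc_ml", "acc_ap", "acc_cc")],
    function(x) sqrt(mean(x^2)), numeric(1)
  )
  rms_a <- sqrt(sum(rms^2))
  if (rms_a == 0) {
    abort("all-zero accelerations: RMS ratios undefined")
  }
  tibble::tibble(
    rmsr_ml = rms[["acc_ml"]] / rms_a,
    rmsr_ap = rms[["acc_ap"]] / rms_a,
    rmsr_cc = rms[["acc_cc"]] / rms_a
  )
}

#' Unbiased autocorrelation via the Wiener–Khinchin theorem
#'
#' FFT-based autocovariance of the mean-removed series (zero-padded to at
#' least twice the length to avoid circular wrap-around), divided by
#' `(n - lag)` (the unbiased correction) and normalized so that the zero-lag
#' coefficient is 1.
#'
#' @param x numeric series (craniocaudal acceleration of one regime).
#' @return numeric vector of autocorrelation coefficients at lags
#'   `0 .. n - 1`.
#' @export
autocorrelation_unbiased <- function(x) {
  n <- length(x)
  if (n < 8) {
    abort("series too short for autocorrelation")
  }
  x <- x - mean(x)
  if (all(x == 0)) {
    abort("zero-variance input: autocorrelation undefined")
  }
  nfft <- stats::nextn(2L * n, 2)
  sp <- fft(c(x, rep(0, nfft - n)))
  raw <- Re(fft(sp * Conj(sp), inverse = TRUE))[seq_len(n)] / nfft
  unb <- raw / (n - (seq_len(n) - 1))
  unb / unb[1]
}

# cadence (step frequency, Hz) as the dominant periodogram frequency of the
# craniocaudal acceleration within the plausible gait band
cadence_estimate <- function(acc_cc, fs, band = c(0.8, 3.5)) {
  pg <- periodogram(acc_cc - mean(acc_cc), fs)
  ok <- pg$freq >= band[1] & pg$freq <= band[2]
  if (!any(ok) || all(pg$power[ok] == 0)) {
    abort("no spectral energy in the gait band: cannot estimate cadence")
  }
  pg$freq[ok][which.max(pg$power[ok])]
}

#' Autocorrelation peaks at one-step and two-step lags
#'
#' P1 is the maximum of the ACF over lags in `[0.5, 1.5]` step periods
#' (one-step lag: step symmetry), P2 over `[1.5, 2.5]` step periods
#' (two-step / one-stride lag: steadiness). Windowing by the cadence avoids
#' noise lobes below the step lag capturing the first peak.
#'
#' @param acf autocorrelation coefficients from
#'   [autocorrelation_unbiased()].
#' @param cadence_hint_hz step frequency in Hz (e.g. the regime's dominant
#'   craniocaudal frequency).
#' @param fs sampling rate in Hz.
#' @param x the series the ACF was computed on (optional). When supplied,
#'   peak heights are evaluated as the support-matched correlation
#'   coefficient at the localized lag, which removes the O(1/cycles)
#'   support-mismatch wobble of the unbiased estimator on short windows;
#'   peak lags always come from the ACF itself.
#' @return list with `p1`, `p2` and the peak lags in samples `lag1`, `lag2`.
#' @export
acf_peaks <- function(acf, cadence_hint_hz, fs, x = NULL) {
  stopifnot(cadence_hint_hz > 0, fs > 0)
  step <- fs / cadence_hint_hz # one step period, in samples
  w1 <- seq.int(max(1L, round(0.5 * step)), round(1.5 * step))
  w2 <- seq.int(round(1.5 * step), round(2.5 * step))
  if (max(w2) + 1L > length(acf)) {
    abort("regime too short: two-step lag window outside ACF support")
  }
  i1 <- w1[which.max(acf[w1 + 1L])]
  i2 <- w2[which.max(acf[w2 + 1L])]
  value_at <- function(lag) {
    if (is.null(x)) refine_peak(acf, lag) else matched_peak(x, lag)
  }
  list(
    p1 = value_at(i1), p2 = value_at(i2),
    lag1 = i1, lag2 = i2
  )
}

# correlation coefficient between the series and its lag-k shift, computed
# on the overlapping support
pearson_at_lag <- function(x, k) {
  n <- length(x)
  if (k <= 0 || k >= n - 1) {
    return(NA_real_)
  }
  a <- x[1:(n - k)]
  b <- x[(k + 1):n]
  if (sd(a) == 0 || sd(b) == 0) {
    return(0)
  }
  stats::cor(a, b)
}

# spline-refined support-matched peak height around an integer lag
matched_peak <- function(x, lag) {
  lags <- seq.int(max(1L, lag - 4L), min(length(x) - 2L, lag + 4L))
  vals <- vapply(lags, pearson_at_lag, numeric(1), x = x)
  if (length(lags) < 4) {
    return(vals[which(lags == lag)])
  }
  f <- stats::splinefun(lags, vals, method = "natural")
  opt <- optimize(f,
    lower = max(min(lags), lag - 1L),
    upper = min(max(lags), lag + 1L), maximum = TRUE
  )
  max(opt$objective, vals[which(lags == lag)])
}

# spline interpolation of the peak value around an interior local maximum;
# the ACF of a band-limited signal (<= 5 Hz at 100 Hz sampling) is smooth on
# the lag grid, so the true peak sits between integer lags whenever the step
# period is not a whole number of samples
refine_peak <- function(acf, lag) {
  i <- lag + 1L
  half <- 4L
  lo <- max(1L, i - half)
  hi <- min(length(acf), i + half)
  if (i <= 1L || i >= length(acf) || acf[i] < acf[i - 1L] ||
    acf[i] < acf[i + 1L]) {
    return(acf[i]) # not an interior local maximum: keep the sample value
  }
  f <- stats::splinefun(lo:hi, acf[lo:hi], method = "natural")
  opt <- optimize(f, lower = max(lo, i - 1L), upper = min(hi, i + 1L),
    maximum = TRUE
  )
  max(opt$objective, acf[i])
}

#' Gait criteria for walking regimes
#'
#' Computes the four gait-quality criteria on each regime span: `rmsr_ml`
#' (stability; lower is better), `rmsr_ap` (sturdiness), `p1cc` (symmetry)
#' and `p2cc` (steadiness), plus the internal `rmsr_cc` and the cadence used
#' for the peak windows.
#'
#' @param rec a filtered [imu_recording()].
#' @param regimes tibble with `start_s`, `end_s` (and optionally `regime`,
#'   `label`; rows are not filtered — pass walking regimes).
#' @param rms_guard_s,acf_guard_s guard bands in seconds excluded at both
#'   span edges (defaults 0.1 and 0.3): spans abut transitions whose content
#'   belongs to neither regime, and the zero-phase 0.5 Hz high-pass edge
#'   smears transition content about half a second into each regime.
#'   Cross-regime phase mixing degrades the correlation criteria at first
#'   order, so they use the wider guard; the energy ratios are only touched
#'   at second order and keep more cycles instead. A guard is skipped when
#'   the span is shorter than 1 s plus twice the guard.
#' @return `regimes` with criterion columns appended.
#' @export
gait_criteria <- function(rec, regimes, rms_guard_s = 0.1, acf_guard_s = 0.3) {
  fs <- imu_rate(rec)
  guarded <- function(i, guard) {
    g <- if (regimes$end_s[i] - regimes$start_s[i] >= 1 + 2 * guard) guard else 0
    regime_samples(rec, regimes$start_s[i] + g, regimes$end_s[i] - g)
  }
  rows <- purrr::map(seq_len(nrow(regimes)), function(i) {
    rr <- rms_ratios(guarded(i, rms_guard_s))
    seg <- guarded(i, acf_guard_s)
    cadence <- cadence_estimate(seg$acc_cc, fs)
    pk <- acf_peaks(
      autocorrelation_unbiased(seg$acc_cc), cadence, fs,
      x = seg$acc_cc
    )
    dplyr::mutate(rr, p1cc = pk$p1, p2cc = pk$p2, cadence_hz = cadence)
  })
  dplyr::bind_cols(regimes, dplyr::bind_rows(rows))
}

criterion_names <- function() {
  c("rmsr_ml", "rmsr_ap", "p1cc", "p2cc")
}

criterion_orientation <- function() {
  # +1: higher is better; -1: lower is better (mediolateral RMS ratio)
  c(rmsr_ml = -1, rmsr_ap = 1, p1cc = 1, p2cc = 1)
}

#' Fit the healthy reference model
#'
#' For each criterion, the mean and SD over all healthy walking regimes, the
#' z-transform `z = (x - mu) / sigma`, and display bounds
#' `x_min`, `x_max`: the 10th and 90th percentiles of the z-scored healthy
#' values (no normality assumed). Requires at least 10 healthy walking
#' regimes.
#'
#' @param criteria tibble of healthy walking-regime criteria (from
#'   [gait_criteria()]).
#' @return an object of class `healthy_model`: tibble with `criterion`,
#'   `mu`, `sigma`, `x_min`, `x_max`, `orientation`.
#' @export
fit_healthy_model <- function(criteria) {
  stopifnot(all(criterion_names() %in% names(criteria)))
  if (nrow(criteria) < 10) {
    abort("need at least 10 healthy walking regimes")
  }
  ori <- criterion_orientation()
  rows <- purrr::map(criterion_names(), function(cn) {
    x <- criteria[[cn]]
    mu <- mean(x)
    sigma <- sd(x)
    if (sigma == 0) {
      abort(sprintf("criterion %s has zero variance over healthy regimes", cn))
    }
    z <- (x - mu) / sigma
    q <- quantile(z, c(0.1, 0.9), names = FALSE)
    tibble::tibble(
      criterion = cn, mu = mu, sigma = sigma,
      x_min = q[1], x_max = q[2], orientation = ori[[cn]]
    )
  })
  structure(dplyr::bind_rows(rows), class = c("healthy_model", class(tibble::tibble())))
}

#' @export
print.healthy_model <- function(x, ...) {
  cat("<healthy_model: per-criterion z-reference with 10/90 percentile bounds>\n")
  NextMethod()
}

#' @describeIn fit_healthy_model tidy method (the per-criterion table).
#' @param x a `healthy_model`.
#' @param ... unused.
#' @export
tidy.healthy_model <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

display_bins <- function() {
  c("well_below", "slightly_below", "within", "slightly_above", "well_above")
}

#' Score regimes against the healthy model
#'
#' Computes per-criterion z-scores, orients them so that higher always means
#' better (the mediolateral RMS ratio is negated), and bins each oriented
#' score against the oriented healthy 10th/90th percentile bounds. "Slightly"
#' below/above extends half the healthy inter-percentile range beyond a
#' bound; past that, scores are "well" below/above.
#'
#' @param criteria tibble from [gait_criteria()] (must carry `regime`).
#' @param model a fitted `healthy_model`.
#' @return long tibble: `regime`, `criterion`, `value`, `z`, `oriented_z`,
#'   `bin` (ordered factor).
#' @export
score_regimes <- function(criteria, model) {
  stopifnot(inherits(model, "healthy_model"))
  ref <- tidy(model)
  long <- tidyr::pivot_longer(
    criteria[, c("regime", criterion_names())],
    cols = dplyr::all_of(criterion_names()),
    names_to = "criterion", values_to = "value"
  )
  long <- dplyr::left_join(long, ref, by = "criterion")
  long <- dplyr::mutate(long,
    z = (.data$value - .data$mu) / .data$sigma,
    oriented_z = .data$orientation * .data$z,
    o_lo = pmin(.data$orientation * .data$x_min, .data$orientation * .data$x_max),
    o_hi = pmax(.data$orientation * .data$x_min, .data$orientation * .data$x_max),
    half = 0.5 * (.data$o_hi - .data$o_lo),
    bin = dplyr::case_when(
      .data$oriented_z < .data$o_lo - .data$half ~ "well_below",
      .data$oriented_z < .data$o_lo ~ "slightly_below",
      .data$oriented_z <= .data$o_hi ~ "within",
      .data$oriented_z <= .data$o_hi + .data$half ~ "slightly_above",
      TRUE ~ "well_above"
    )
  )
  tibble::as_tibble(dplyr::transmute(long,
    regime = .data$regime, criterion = .data$criterion,
    value = .data$value, z = .data$z, oriented_z = .data$oriented_z,
    bin = factor(.data$bin, levels = display_bins(), ordered = TRUE)
  ))
}

#' Persist / load the healthy model as JSON
#'
#' @param model a `healthy_model`.
#' @param path JSON path.
#' @export
write_healthy_model <- function(model, path) {
  jsonlite::write_json(tidy(model), path, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_healthy_model
#' @export
read_healthy_model <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    tibble::as_tibble(df),
    class = c("healthy_model", class(tibble::tibble()))
  )
}
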