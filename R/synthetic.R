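#' Gait-quality knobs for the synthetic generator
#'
#' Parameters that shape a synthetic walking block and map monotonically onto
#' the four gait criteria: `amp_ml` drives the stability criterion (RMSR_ML),
#' `amp_ap` drives sturdiness (RMSR_AP), `asymmetry_delta` (a stride-frequency
#' admixture that breaks step symmetry) lowers the one-step autocorrelation
#' peak P1CC, and `timing_jitter_sd` (step-to-step period noise) lowers the
#' two-step peak P2CC.
#'
#' @param step_freq_hz cadence in steps/s, in \[1.2, 2.5\] (default 1.9, a
#'   typical adult cadence).
#' @param amp_cc,amp_ap,amp_ml acceleration amplitudes in g of the
#'   craniocaudal, anteroposterior and mediolateral oscillations.
#' @param asymmetry_delta relative amplitude in \[0, 1\] of the
#'   stride-frequency (half-cadence) component added to the craniocaudal
#'   channel.
#' @param timing_jitter_sd SD in seconds of the step-to-step period noise.
#' @param noise_sd white sensor noise SD in g (gyroscope noise is scaled by
#'   30 deg/s per g).
#' @return a list of class `gait_knobs`.
#' @export
gait_knobs <- function(step_freq_hz = 1.9, amp_cc = 0.35, amp_ap = 0.20,
                       amp_ml = 0.12, asymmetry_delta = 0.05,
                       timing_jitter_sd = 0.01, noise_sd = 0.02) {
  if (step_freq_hz < 1.2 || step_freq_hz > 2.5) {
    abort("step_freq_hz must lie in [1.2, 2.5]")
  }
  if (any(c(amp_cc, amp_ap, amp_ml) < 0)) {
    abort("amplitudes must be non-negative")
  }
  if (asymmetry_delta < 0 || asymmetry_delta > 1) {
    abort("asymmetry_delta must lie in [0, 1]")
  }
  if (timing_jitter_sd < 0 || noise_sd < 0) {
    abort("noise parameters must be non-negative")
  }
  structure(
    list(
      step_freq_hz = step_freq_hz, amp_cc = amp_cc, amp_ap = amp_ap,
      amp_ml = amp_ml, asymmetry_delta = asymmetry_delta,
      timing_jitter_sd = timing_jitter_sd, noise_sd = noise_sd
    ),
    class = "gait_knobs"
  )
}

#' Protocol configuration for the synthetic generator
#'
#' The default sequence reproduces the annotated semi-controlled circuit: five
#' walking phases W1--W5 interleaved with activities A1 (door opening and
#' 90-degree turn) and A2 (short stairs) which are non-sedentary, and A3--A5
#' (leaning, standing still, sitting still) which are sedentary, for a total
#' of exactly 6 minutes.
#'
#' @param regime_sequence tibble with columns `regime_id` (W1..W5, A1..A5) and
#'   `duration_s`.
#' @param sampling_rate_hz sampling rate in Hz (default 100).
#' @param total_duration_s total protocol duration; must equal the sum of
#'   `duration_s` (default 360).
#' @return a list of class `protocol_config`.
#' @export
protocol_config <- function(regime_sequence = default_regime_sequence(),
                            sampling_rate_hz = 100,
                            total_duration_s = sum(regime_sequence$duration_s)) {
  stopifnot(all(c("regime_id", "duration_s") %in% names(regime_sequence)))
  if (any(regime_sequence$duration_s <= 0)) {
    abort("regime durations must be positive")
  }
  if (abs(sum(regime_sequence$duration_s) - total_duration_s) > 1e-9) {
    abort("sum of regime durations must equal total_duration_s")
  }
  structure(
    list(
      regime_sequence = tibble::as_tibble(regime_sequence),
      sampling_rate_hz = sampling_rate_hz,
      total_duration_s = total_duration_s
    ),
    class = "protocol_config"
  )
}

#' @rdname protocol_config
#' @export
default_regime_sequence <- function() {
  tibble::tibble(
    regime_id = c("W1", "A1", "W2", "W3", "A2", "A3", "A4", "A5", "W4", "W5"),
    duration_s = c(50, 15, 40, 40, 25, 20, 20, 30, 60, 60)
  )
}

#' Regime label for a protocol regime id
#'
#' W* are walking; A1 and A2 involve movement (non-sedentary); A3, A4 and A5
#' are motionless (sedentary).
#'
#' @param regime_id character vector of ids like "W1", "A3".
#' @return character vector of labels.
#' @export
regime_label <- function(regime_id) {
  dplyr::case_when(
    grepl("^W", regime_id) ~ "walking",
    regime_id %in% c("A1", "A2") ~ "non_sedentary",
    grepl("^A", regime_id) ~ "sedentary",
    TRUE ~ NA_character_
  )
}

# six-channel block as a plain list of numeric vectors
new_block <- function(n) {
  out <- lapply(imu_channels(), function(ch) numeric(n))
  names(out) <- imu_channels()
  out
}

#' Generate one synthetic walking block
#'
#' The craniocaudal acceleration is a harmonic series (fundamental plus two
#' harmonics) at the step frequency, with a stride-frequency admixture of
#' relative amplitude `asymmetry_delta`; the mediolateral channel oscillates
#' at stride frequency, the anteroposterior at step frequency. Step periods
#' are jittered with SD `timing_jitter_sd` (phase is piecewise-linear between
#' jittered step boundaries) and white noise of SD `noise_sd` is added to all
#' channels.
#'
#' @param knobs a [gait_knobs()].
#' @param duration_s block duration in seconds (>= 3, one STFT window).
#' @param rate sampling rate in Hz.
#' @return list of six numeric channels (`acc_cc`, ..., `gyr_ap`).
#' @export
generate_walking_segment <- function(knobs, duration_s, rate = 100) {
  if (duration_s < 3) {
    abort("walking blocks must last at least 3 s (one STFT window)")
  }
  n <- round(duration_s * rate)
  t <- (seq_len(n) - 1) / rate
  f <- knobs$step_freq_hz
  if (knobs$timing_jitter_sd == 0) {
    phase <- 2 * pi * f * t
  } else {
    n_steps <- ceiling(duration_s * f) + 2L
    periods <- pmax(1 / f + rnorm(n_steps, 0, knobs$timing_jitter_sd), 0.3 / f)
    bounds <- c(0, cumsum(periods))
    phase <- stats::approx(bounds, 2 * pi * (0:n_steps), xout = t, rule = 2)$y
  }
  b <- new_block(n)
  d <- knobs$asymmetry_delta
  b$acc_cc <- knobs$amp_cc *
    (sin(phase) + 0.3 * sin(2 * phase) + 0.15 * sin(3 * phase) +
      d * sin(phase / 2))
  b$acc_ml <- knobs$amp_ml * (sin(phase / 2 + 1.0) + 0.1 * sin(phase + 0.4))
  b$acc_ap <- knobs$amp_ap * (sin(phase + 0.8) + 0.3 * sin(2 * phase + 0.2))
  b$gyr_cc <- 8 * sin(phase / 2 + 2.0)
  b$gyr_ml <- 25 * sin(phase + 1.2) + 8 * sin(2 * phase + 0.6)
  b$gyr_ap <- 12 * sin(phase / 2 + 0.5)
  add_noise(b, knobs$noise_sd)
}

add_noise <- function(b, noise_sd) {
  if (noise_sd > 0) {
    n <- length(b$acc_cc)
    for (ch in imu_channels()) {
      sdv <- if (startsWith(ch, "acc")) noise_sd else 30 * noise_sd
      b[[ch]] <- b[[ch]] + rnorm(n, 0, sdv)
    }
  }
  b
}

#' Generate one synthetic activity block
#'
#' Sedentary blocks are low-variance sensor noise plus a slow drift
#' (postural sway); non-sedentary blocks are broadband bursts of band-limited
#' noise under random smooth envelopes, with spectral energy overlapping the
#' gait band but no sustained periodicity. Every activity block starts with a
#' ~0.8 s postural-transition transient (the movement of sitting down,
#' leaning, grabbing a door) so that transitions between consecutive still
#' activities remain visible to a spectrogram, as they are in real protocols.
#'
#' @param kind `"sedentary"` or `"non_sedentary"`.
#' @param duration_s block duration in seconds (>= 1).
#' @param rate sampling rate in Hz.
#' @param noise_sd sensor noise SD in g.
#' @param intensity sustained sway amplitude in g for sedentary blocks
#'   (activities differ: leaning sways more than standing, standing more
#'   than sitting); drawn at random when `NULL`.
#' @return list of six numeric channels.
#' @export
generate_activity_segment <- function(kind, duration_s, rate = 100,
                                      noise_sd = 0.02, intensity = NULL) {
  kind <- match.arg(kind, c("sedentary", "non_sedentary"))
  if (duration_s < 1) {
    abort("activity blocks must last at least 1 s")
  }
  n <- round(duration_s * rate)
  t <- (seq_len(n) - 1) / rate
  b <- new_block(n)
  if (kind == "sedentary") {
    # slow postural sway plus in-band micro-adjustments (weight shifting)
    # whose level depends on the activity: leaning > standing > sitting
    f_sway <- runif(1, 0.05, 0.15)
    amp <- if (is.null(intensity)) runif(1, 0.004, 0.010) else intensity
    bf <- signal::butter(2, c(0.5, 4) / (rate / 2), type = "pass")
    for (ch in c("acc_cc", "acc_ml", "acc_ap")) {
      b[[ch]] <- amp * sin(2 * pi * f_sway * t + runif(1, 0, 2 * pi)) +
        0.8 * amp * bandnoise(bf, n) + rnorm(n, 0, 0.003)
    }
    for (ch in c("gyr_cc", "gyr_ml", "gyr_ap")) {
      b[[ch]] <- 100 * amp * sin(2 * pi * f_sway * t + runif(1, 0, 2 * pi)) +
        250 * amp * bandnoise(bf, n) + rnorm(n, 0, 0.3)
    }
  } else {
    bf <- signal::butter(2, c(0.5, 5) / (rate / 2), type = "pass")
    env <- burst_envelope(t, duration_s)
    for (ch in c("acc_cc", "acc_ml", "acc_ap")) {
      b[[ch]] <- 0.10 * env * bandnoise(bf, n) + rnorm(n, 0, 0.004)
    }
    for (ch in c("gyr_cc", "gyr_ml", "gyr_ap")) {
      b[[ch]] <- 12 * env * bandnoise(bf, n) + rnorm(n, 0, 0.4)
    }
  }
  b <- add_transition_pulse(b, rate)
  add_noise(b, noise_sd)
}

# band-limited unit-SD noise
bandnoise <- function(bf, n) {
  x <- as.numeric(signal::filter(bf, rnorm(n)))
  s <- sd(x)
  if (s == 0) x else x / s
}

# random smooth burst envelope: dense Gaussian bumps (~one per 1.2 s) so the
# block is nonstationary at sub-second scale but homogeneous at window scale
burst_envelope <- function(t, duration_s) {
  k <- max(4L, round(duration_s / 0.8))
  centers <- runif(k, 0, duration_s)
  widths <- runif(k, 0.25, 0.5)
  heights <- runif(k, 0.5, 1.5)
  env <- rep(0.35, length(t))
  for (j in seq_len(k)) {
    env <- env + heights[j] * exp(-0.5 * ((t - centers[j]) / widths[j])^2)
  }
  env / max(env)
}

# ~0.8 s movement transient at block start (posture change at the regime
# boundary: sitting down, leaning in, grabbing a door)
add_transition_pulse <- function(b, rate) {
  n <- length(b$acc_cc)
  t <- (seq_len(n) - 1) / rate
  env <- exp(-0.5 * ((t - 0.3) / 0.2)^2)
  f <- runif(1, 1.2, 2.2)
  for (ch in c("acc_cc", "acc_ml", "acc_ap")) {
    b[[ch]] <- b[[ch]] + 0.08 * env * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
  }
  b$gyr_cc <- b$gyr_cc + 12 * env * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
  b$gyr_ml <- b$gyr_ml + 8 * env * sin(2 * pi * f * t + runif(1, 0, 2 * pi))
  b
}

# 1 s Gaussian-envelope yaw pulse (a turn) centered at time `center_s`
add_turn_pulse <- function(channel, rate, center_s, amplitude = 15) {
  n <- length(channel)
  t <- (seq_len(n) - 1) / rate
  channel + amplitude * exp(-0.5 * ((t - center_s) / 0.25)^2)
}

#' Generate a full annotated protocol recording
#'
#' Concatenates per-regime blocks in the configured order with 0.1 s
#' raised-cosine cross-fades at block joins (the ground-truth changepoint sits
#' at the fade midpoint, i.e. the block boundary), and adds 1 s
#' Gaussian-envelope craniocaudal angular-velocity pulses at the start and end
#' of each walking regime (turns at lap corners).
#'
#' @param config a [protocol_config()].
#' @param knobs a [gait_knobs()].
#' @param seed integer seed; the output is bit-reproducible given
#'   `(config, knobs, seed)`.
#' @param subject_id optional identifier stored in the annotation.
#' @param healthy logical flag stored in the annotation.
#' @return a list of class `annotated_recording`: `recording` (an
#'   [imu_recording()]), `true_changepoints_s`, `regime_labels`, and a
#'   `regimes` tibble (`regime_id`, `start_s`, `end_s`, `label`).
#' @export
generate_protocol <- function(config = protocol_config(),
                              knobs = gait_knobs(), seed = 1,
                              subject_id = "S1", healthy = TRUE) {
  set.seed(seed)
  rate <- config$sampling_rate_hz
  seqs <- config$regime_sequence
  labels <- regime_label(seqs$regime_id)
  if (anyNA(labels)) {
    abort("regime ids must match W* or A*")
  }
  sway <- c(A3 = 0.035, A4 = 0.015, A5 = 0.004) # leaning > standing > sitting
  blocks <- vector("list", nrow(seqs))
  for (i in seq_len(nrow(seqs))) {
    if (labels[i] == "walking") {
      # inter-lap variability: each walking leg has its own pace and vigor
      kn <- knobs
      kn$step_freq_hz <- min(2.5, max(1.2, knobs$step_freq_hz * runif(1, 0.93, 1.07)))
      kn$amp_cc <- knobs$amp_cc * runif(1, 0.8, 1.2)
      kn$amp_ap <- knobs$amp_ap * runif(1, 0.8, 1.2)
      kn$amp_ml <- knobs$amp_ml * runif(1, 0.8, 1.2)
      kn$asymmetry_delta <- min(1, knobs$asymmetry_delta * runif(1, 0.6, 1.4))
      kn$timing_jitter_sd <- knobs$timing_jitter_sd * runif(1, 0.7, 1.3)
      blk <- generate_walking_segment(kn, seqs$duration_s[i], rate)
      # turns happen at the regime boundaries (lap corners)
      blk$gyr_cc <- add_turn_pulse(blk$gyr_cc, rate, 0)
      blk$gyr_cc <- add_turn_pulse(blk$gyr_cc, rate, seqs$duration_s[i])
    } else {
      kind <- if (labels[i] == "sedentary") "sedentary" else "non_sedentary"
      blk <- generate_activity_segment(kind, seqs$duration_s[i], rate,
        noise_sd = knobs$noise_sd,
        intensity = if (seqs$regime_id[i] %in% names(sway)) {
          sway[[seqs$regime_id[i]]]
        } else {
          NULL
        }
      )
    }
    blocks[[i]] <- crossfade_edges(blk, rate, fade_s = 0.05)
    names(blocks)[i] <- seqs$regime_id[i]
  }
  channels <- lapply(imu_channels(), function(ch) {
    unlist(lapply(blocks, `[[`, ch), use.names = FALSE)
  })
  names(channels) <- imu_channels()
  n <- length(channels$acc_cc)
  rec <- imu_recording(
    tibble::as_tibble(c(list(time_s = (seq_len(n) - 1) / rate), channels)),
    sampling_rate_hz = rate
  )
  ends <- cumsum(seqs$duration_s)
  regimes <- tibble::tibble(
    regime = seq_len(nrow(seqs)),
    regime_id = seqs$regime_id,
    start_s = c(0, head(ends, -1)),
    end_s = ends,
    label = labels
  )
  structure(
    list(
      recording = rec,
      true_changepoints_s = head(ends, -1),
      regime_labels = labels,
      regimes = regimes,
      subject_id = subject_id,
      healthy = healthy
    ),
    class = "annotated_recording"
  )
}

# raised-cosine fade-in/out over `fade_s` at both block edges, so abutted
# blocks form a 2*fade_s cross-fade centered on the join
crossfade_edges <- function(b, rate, fade_s = 0.05) {
  m <- round(fade_s * rate)
  n <- length(b$acc_cc)
  if (m < 1 || n < 2 * m) {
    return(b)
  }
  ramp <- 0.5 - 0.5 * cos(pi * (seq_len(m) - 0.5) / m)
  for (ch in imu_channels()) {
    b[[ch]][seq_len(m)] <- b[[ch]][seq_len(m)] * ramp
    b[[ch]][n - m + seq_len(m)] <- b[[ch]][n - m + seq_len(m)] * rev(ramp)
  }
  b
}

#' @export
print.annotated_recording <- function(x, ...) {
  cat(sprintf(
    "<annotated_recording '%s': %d regimes, %d changepoints, %.1f s, healthy=%s>\n",
    x$subject_id, nrow(x$regimes), length(x$true_changepoints_s),
    imu_duration(x$recording), x$healthy
  ))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Healthy subjects draw their knobs near the defaults; pathological subjects
#' additionally degrade one gait aspect, cycling over four subtypes:
#' `stability` (mediolateral amplitude at least doubled), `sturdiness`
#' (anteroposterior amplitude shrunk), `symmetry` (large stride-frequency
#' admixture) and `steadiness` (large step-timing jitter).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param seed integer seed.
#' @param healthy_fraction fraction of healthy subjects (default 0.7,
#'   mirroring a 21-healthy / 9-pathological cohort).
#' @param config a [protocol_config()] shared by all subjects.
#' @return tibble with one row per subject: `subject_id`, `healthy`,
#'   `subtype`, `knobs` (list-column), `recording` (list-column of
#'   `annotated_recording`s).
#' @export
generate_cohort <- function(n_subjects, seed = 1, healthy_fraction = 0.7,
                            config = protocol_config()) {
  if (n_subjects < 2) {
    abort("need at least 2 subjects")
  }
  if (healthy_fraction <= 0 || healthy_fraction >= 1) {
    abort("healthy_fraction must lie strictly between 0 and 1")
  }
  n_healthy <- max(1L, min(n_subjects - 1L, round(n_subjects * healthy_fraction)))
  set.seed(seed)
  subject_seeds <- sample.int(2^20, n_subjects)
  subtypes <- c("stability", "sturdiness", "symmetry", "steadiness")
  rows <- purrr::map(seq_len(n_subjects), function(i) {
    healthy <- i <= n_healthy
    set.seed(subject_seeds[i])
    kn <- draw_healthy_knobs()
    subtype <- NA_character_
    if (!healthy) {
      subtype <- subtypes[(i - n_healthy - 1L) %% length(subtypes) + 1L]
      kn <- degrade_knobs(kn, subtype)
    }
    id <- sprintf("S%02d", i)
    tibble::tibble(
      subject_id = id, healthy = healthy, subtype = subtype,
      knobs = list(kn),
      recording = list(generate_protocol(config, kn,
        seed = subject_seeds[i],
        subject_id = id, healthy = healthy
      ))
    )
  })
  dplyr::bind_rows(rows)
}

draw_healthy_knobs <- function() {
  gait_knobs(
    step_freq_hz = runif(1, 1.7, 2.1),
    amp_cc = rnorm(1, 0.35, 0.03),
    amp_ap = rnorm(1, 0.20, 0.015),
    amp_ml = rnorm(1, 0.12, 0.010),
    asymmetry_delta = runif(1, 0, 0.1),
    timing_jitter_sd = runif(1, 0.004, 0.025),
    noise_sd = 0.03
  )
}

degrade_knobs <- function(kn, subtype) {
  switch(subtype,
    stability = {
      kn$amp_ml <- max(kn$amp_ml * runif(1, 2.5, 3.2), 0.26)
    },
    sturdiness = {
      kn$amp_ap <- kn$amp_ap * runif(1, 0.3, 0.45)
    },
    symmetry = {
      kn$asymmetry_delta <- runif(1, 0.40, 0.60)
    },
    steadiness = {
      kn$timing_jitter_sd <- runif(1, 0.05, 0.08)
    },
    abort(sprintf("unknown pathological subtype '%s'", subtype))
  )
  kn
}
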