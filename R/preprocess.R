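#' Zero-phase Butterworth bandpass filter
#'
#' Filters all six channels identically with a Butterworth bandpass of the
#' given design order, applied forward and backward (`signal::filtfilt`) so
#' that autocorrelation peak lags downstream are not phase-distorted. The
#' magnitude response is therefore that of an effective order `2 * order`
#' filter; the design order is what is quoted.
#'
#' @param rec an [imu_recording()].
#' @param low,high band edges in Hz (defaults 0.5 and 5).
#' @param order Butterworth design order (default 4).
#' @return the filtered [imu_recording()].
#' @export
bandpass <- function(rec, low = 0.5, high = 5, order = 4) {
  fs <- imu_rate(rec)
  if (high >= fs / 2) {
    abort("high cutoff must be below the Nyquist frequency")
  }
  if (low <= 0 || low >= high) {
    abort("need 0 < low < high")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  out <- rec
  for (ch in imu_channels()) {
    out[[ch]] <- as.numeric(signal::filtfilt(bf, rec[[ch]]))
  }
  imu_recording(out, sampling_rate_hz = fs)
}

#' Short-time Fourier representation of a recording
#'
#' Builds the multivariate signal segmented by [pelt_segment()]: the
#' craniocaudal angular velocity and anteroposterior acceleration are each
#' normalized to zero mean and unit variance over the whole recording, cut
#' into Hann-windowed frames (3 s window, 0.1 s hop), and the STFT magnitudes
#' in the open band 0 < f < 5 Hz are kept. At 100 Hz this retains 14 bins per
#' channel (bin spacing 1/3 Hz), concatenated to d = 28 per frame, ordered
#' gyr_cc bins then acc_ap bins.
#'
#' @param rec an [imu_recording()] (normally already bandpassed).
#' @param window_s,hop_s STFT window and hop in seconds.
#' @param band upper band edge in Hz; bins with `0 < f < band` are kept
#'   (strict inequalities).
#' @return an object of class `spectral_series`: list with `frames` (n x d
#'   magnitude matrix), `frame_times_s` (frame centers), `window_s`, `hop_s`,
#'   `band_hz`, `fs`.
#' @export
spectral_series <- function(rec, window_s = 3, hop_s = 0.1, band = 5) {
  fs <- imu_rate(rec)
  win <- round(window_s * fs)
  hop <- round(hop_s * fs)
  n_samp <- nrow(rec)
  if (n_samp < win) {
    abort("recording shorter than one STFT window")
  }
  blocks <- lapply(list(rec$gyr_cc, rec$acc_ap), function(x) {
    s <- sd(x)
    if (s == 0) {
      warn("zero-variance channel: normalization skipped (centered only)")
      x - mean(x)
    } else {
      (x - mean(x)) / s
    }
  })
  n_frames <- (n_samp - win) %/% hop + 1
  starts <- (seq_len(n_frames) - 1L) * hop
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / win)
  # bins with 0 < k * fs / win < band, strict on both sides
  k <- seq_len(win %/% 2)
  keep <- k[k * fs / win < band - 1e-12]
  frames <- matrix(0, n_frames, 2L * length(keep))
  idx <- outer(seq_len(win), starts, "+") # win x n_frames sample indices
  for (b in 1:2) {
    seg <- matrix(blocks[[b]][idx], nrow = win) * hann
    sp <- mvfft(seg)
    mag <- Mod(sp[keep + 1L, , drop = FALSE]) # k is 0-based bin index
    frames[, (b - 1L) * length(keep) + seq_along(keep)] <- t(mag)
  }
  colnames(frames) <- c(
    paste0("gcc_", sprintf("%.3f", keep * fs / win)),
    paste0("aap_", sprintf("%.3f", keep * fs / win))
  )
  structure(
    list(
      frames = frames,
      frame_times_s = rec$time_s[1] + starts / fs + window_s / 2,
      window_s = window_s,
      hop_s = hop_s,
      band_hz = band,
      fs = fs
    ),
    class = "spectral_series"
  )
}

#' @export
print.spectral_series <- function(x, ...) {
  cat(sprintf(
    "<spectral_series: %d frames x %d bins, window %.3g s, hop %.3g s, band (0, %g) Hz>\n",
    nrow(x$frames), ncol(x$frames), x$window_s, x$hop_s, x$band_hz
  ))
  invisible(x)
}

#' @export
as.matrix.spectral_series <- function(x, ...) x$frames

#' Tidy a spectral series into a long tibble
#'
#' @param x a `spectral_series`.
#' @param ... unused.
#' @return tibble with columns `frame`, `time_s`, `bin`, `magnitude`.
#' @export
tidy.spectral_series <- function(x, ...) {
  tibble::tibble(
    frame = rep(seq_len(nrow(x$frames)), times = ncol(x$frames)),
    time_s = rep(x$frame_times_s, times = ncol(x$frames)),
    bin = rep(colnames(x$frames), each = nrow(x$frames)),
    magnitude = as.numeric(x$frames)
  )
}
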