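frames_matrix <- function(y) {
  if (inherits(y, "spectral_series")) {
    return(y$frames)
  }
  if (is.matrix(y)) {
    return(y)
  }
  if (is.numeric(y)) {
    return(matrix(y, ncol = 1))
  }
  abort("y must be a spectral_series, matrix, or numeric vector")
}

#' Empirical quadratic cost of one segment
#'
#' Sum over the half-open frame range `[a, b)` of squared deviations from the
#' segment's empirical mean, computed in O(1) per call from cumulative sums.
#' Frame indices are 0-based.
#'
#' @param y a `spectral_series`, matrix (frames x dims), or numeric vector.
#' @param a,b 0-based segment bounds, `0 <= a < b <= n`.
#' @return non-negative cost.
#' @export
segment_cost <- function(y, a, b) {
  m <- frames_matrix(y)
  n <- nrow(m)
  if (!(a >= 0 && a < b && b <= n)) {
    abort("need 0 <= a < b <= n (empty segments are not allowed)")
  }
  cs <- cost_cache(m)
  segment_cost_cached(cs, a, b)
}

cost_cache <- function(m) {
  list(
    S1 = rbind(0, apply(m, 2, cumsum)),
    s2 = c(0, cumsum(rowSums(m^2)))
  )
}

segment_cost_cached <- function(cs, a, b) {
  d1 <- cs$S1[b + 1, ] - cs$S1[a + 1, ]
  (cs$s2[b + 1] - cs$s2[a + 1]) - sum(d1^2) / (b - a)
}

#' Penalized risk of a segmentation
#'
#' Total within-segment quadratic cost plus `beta` times the number of
#' breakpoints.
#'
#' @inheritParams segment_cost
#' @param breakpoints sorted 0-based frame indices strictly inside `(0, n)`;
#'   a `gait_segmentation` is also accepted.
#' @param beta penalty, > 0.
#' @return the penalized risk.
#' @export
penalized_risk <- function(y, breakpoints, beta) {
  if (inherits(breakpoints, "gait_segmentation")) {
    breakpoints <- breakpoints$breakpoints
  }
  m <- frames_matrix(y)
  n <- nrow(m)
  stopifnot(beta > 0)
  check_breakpoints(breakpoints, n)
  cs <- cost_cache(m)
  bounds <- c(0, breakpoints, n)
  cost <- sum(vapply(
    seq_len(length(bounds) - 1),
    function(k) segment_cost_cached(cs, bounds[k], bounds[k + 1]),
    numeric(1)
  ))
  cost + beta * length(breakpoints)
}

check_breakpoints <- function(bp, n) {
  if (length(bp) > 0 &&
    (any(bp <= 0) || any(bp >= n) || any(diff(bp) <= 0))) {
    abort("breakpoints must be strictly increasing and interior to (0, n)")
  }
  invisible(bp)
}

new_segmentation <- function(breakpoints, n, beta, min_size, risk) {
  structure(
    list(
      breakpoints = as.integer(breakpoints), n = as.integer(n),
      beta = beta, min_size = as.integer(min_size), risk = risk
    ),
    class = "gait_segmentation"
  )
}

#' @export
print.gait_segmentation <- function(x, ...) {
  cat(sprintf(
    "<gait_segmentation: %d breakpoints over %d frames (beta=%.4g, risk=%.6g)>\n",
    length(x$breakpoints), x$n, x$beta, x$risk
  ))
  if (length(x$breakpoints) > 0) {
    cat(" frames:", paste(x$breakpoints, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Exact penalized change-point detection (PELT)
#'
#' Returns the global minimizer of [penalized_risk()] over all segmentations
#' whose segments contain at least `min_size` frames; the number of
#' breakpoints is a free output. The pruned dynamic program is exact for this
#' additive quadratic cost. Ties among optima are broken toward fewer,
#' earlier breakpoints.
#'
#' @inheritParams segment_cost
#' @param beta penalty, > 0.
#' @param min_size minimum segment length in frames (default 2, i.e. 0.2 s at
#'   the default hop).
#' @return a `gait_segmentation`: 0-based interior breakpoints, `n`, `beta`,
#'   `min_size` and the attained penalized risk.
#' @export
pelt_segment <- function(y, beta, min_size = 2) {
  m <- frames_matrix(y)
  n <- nrow(m)
  stopifnot(beta > 0, min_size >= 1)
  if (n < 2 * min_size) {
    abort("signal too short: need at least 2 * min_size frames")
  }
  res <- pelt_core(m, beta, as.integer(min_size))
  new_segmentation(res$breakpoints, n, beta, min_size, res$risk)
}

#' Exhaustive dynamic-program segmentation (test oracle)
#'
#' The same objective as [pelt_segment()] solved by the unpruned O(n^2)
#' dynamic program in pure R. Used to certify the pruned solver; guarded to
#' n <= 2000 frames.
#'
#' @inheritParams pelt_segment
#' @return a `gait_segmentation`.
#' @export
brute_force_segment <- function(y, beta, min_size = 2) {
  m <- frames_matrix(y)
  n <- nrow(m)
  stopifnot(beta > 0, min_size >= 1)
  if (n > 2000) {
    abort("brute_force_segment is guarded to n <= 2000")
  }
  if (n < 2 * min_size) {
    abort("signal too short: need at least 2 * min_size frames")
  }
  cs <- cost_cache(m)
  f <- rep(Inf, n + 1)
  prev <- rep(-1L, n + 1)
  f[1] <- -beta
  for (t in seq(min_size, n)) {
    starts <- c(0L, seq_len(max(0L, t - 2L * min_size + 1L)) + min_size - 1L)
    starts <- starts[starts <= t - min_size]
    vals <- vapply(
      starts,
      function(s) f[s + 1] + segment_cost_cached(cs, s, t) + beta,
      numeric(1)
    )
    i <- which.min(vals)
    f[t + 1] <- vals[i]
    prev[t + 1] <- starts[i]
  }
  bps <- integer(0)
  t <- prev[n + 1]
  while (t > 0) {
    bps <- c(t, bps)
    t <- prev[t + 1]
  }
  new_segmentation(bps, n, beta, min_size, f[n + 1])
}

#' Convert breakpoint frame indices to seconds
#'
#' A breakpoint is the 0-based index of the first frame of the new regime;
#' its time is that frame's center, `frame_times_s[t_k]`.
#'
#' @param segmentation a `gait_segmentation` or integer vector of 0-based
#'   frame indices.
#' @param spectral the `spectral_series` the segmentation was computed on.
#' @return numeric vector of breakpoint times in seconds.
#' @export
frames_to_seconds <- function(segmentation, spectral) {
  bp <- if (inherits(segmentation, "gait_segmentation")) {
    segmentation$breakpoints
  } else {
    as.integer(segmentation)
  }
  spectral$frame_times_s[bp + 1L]
}

#' Convert breakpoint seconds to the nearest frame index
#'
#' Inverse of [frames_to_seconds()] up to hop quantization (error at most
#' half a hop); results are clamped to the interior `(0, n)`.
#'
#' @param seconds numeric breakpoint times.
#' @param spectral a `spectral_series`.
#' @return integer vector of 0-based frame indices.
#' @export
seconds_to_frames <- function(seconds, spectral) {
  n <- nrow(spectral$frames)
  idx <- vapply(
    seconds,
    function(s) which.min(abs(spectral$frame_times_s - s)) - 1L,
    integer(1)
  )
  pmin(pmax(idx, 1L), n - 1L)
}

#' @describeIn pelt_segment tidy method: one row per segment with frame and
#'   time spans.
#' @param x a `gait_segmentation`.
#' @param spectral optional `spectral_series` for time columns.
#' @param ... unused.
#' @export
tidy.gait_segmentation <- function(x, spectral = NULL, ...) {
  bounds <- c(0L, x$breakpoints, x$n)
  out <- tibble::tibble(
    segment = seq_len(length(bounds) - 1),
    start_frame = bounds[-length(bounds)],
    end_frame = bounds[-1]
  )
  if (!is.null(spectral)) {
    ft <- spectral$frame_times_s
    out$start_s <- ft[out$start_frame + 1L]
    out$end_s <- c(ft[x$breakpoints + 1L], ft[x$n] + spectral$hop_s)
  }
  out
}

#' @describeIn pelt_segment glance method: one-row summary.
#' @export
glance.gait_segmentation <- function(x, ...) {
  tibble::tibble(
    n_frames = x$n, n_breakpoints = length(x$breakpoints),
    beta = x$beta, min_size = x$min_size, risk = x$risk
  )
}
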