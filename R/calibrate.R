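#' Supervised calibration of the segmentation penalty
#'
#' Learns the penalty `beta` from expert-annotated recordings by minimizing
#' the excess penalized risk of the expert segmentation over the solver's
#' optimum, `gap_i(beta) = R_beta(y_i, truth_i) - R_beta(y_i, PELT_beta(y_i))`,
#' averaged over the annotated signals. The gap is non-negative by optimality
#' of the solver and its minimizer is the penalty at which the solver best
#' reproduces the expert's segmentation scale.
#'
#' The objective has flat steps in `beta` (the solver's output is piecewise
#' constant), so the search is seeded with a `grid_points`-point grid on
#' log10(beta) spanning `search_exponents`, scaled by the mean per-frame
#' variance of the signals, and Brent's method then refines the best grid
#' bracket. With `per_signal = TRUE` a penalty is fitted to each signal
#' separately and aggregated by the median.
#'
#' @param annotated list of annotated series; each element is a list with
#'   `spectral` (a `spectral_series` or matrix) and `breakpoints` (0-based
#'   frame indices) or `breakpoints_s` (seconds, snapped to the nearest
#'   frame).
#' @param min_size minimum segment length in frames for the solver.
#' @param search_exponents log10 range searched, relative to the variance
#'   scale (default `c(-4, 4)`).
#' @param grid_points number of seeding grid points (default 25).
#' @param per_signal fit one penalty per signal and aggregate by median?
#' @return an object of class `penalty_calibration`: `beta_opt`,
#'   `objective_value` (mean gap at the optimum), `search_interval`,
#'   `per_signal_gaps` (tibble: signal, beta, gap), `per_signal` flag.
#' @export
calibrate_penalty <- function(annotated, min_size = 2,
                              search_exponents = c(-4, 4), grid_points = 25,
                              per_signal = FALSE) {
  if (length(annotated) < 1) {
    abort("need at least one annotated series")
  }
  prepped <- purrr::map(annotated, function(a) {
    m <- frames_matrix(a$spectral)
    bp <- a$breakpoints
    if (is.null(bp)) {
      if (is.null(a$breakpoints_s) || !inherits(a$spectral, "spectral_series")) {
        abort("each annotated element needs breakpoints or breakpoints_s + spectral_series")
      }
      bp <- seconds_to_frames(a$breakpoints_s, a$spectral)
    }
    check_breakpoints(bp, nrow(m))
    cs <- cost_cache(m)
    bounds <- c(0, bp, nrow(m))
    truth_cost <- sum(vapply(
      seq_len(length(bounds) - 1),
      function(k) segment_cost_cached(cs, bounds[k], bounds[k + 1]),
      numeric(1)
    ))
    list(m = m, k_true = length(bp), truth_cost = truth_cost)
  })
  # gap for one signal at a given beta; both risks share the beta*K terms
  gap_one <- function(p, beta) {
    fit <- pelt_core(p$m, beta, as.integer(min_size))
    (p$truth_cost + beta * p$k_true) - fit$risk
  }
  scale <- mean(vapply(
    prepped,
    function(p) segment_cost_cached(cost_cache(p$m), 0, nrow(p$m)) / nrow(p$m),
    numeric(1)
  ))
  scale <- max(scale, .Machine$double.eps)
  log_grid <- seq(search_exponents[1], search_exponents[2],
    length.out = grid_points
  ) + log10(scale)
  interval <- 10^range(log_grid)

  fit_joint <- function(prepped_subset) {
    objective <- function(logb) {
      mean(vapply(prepped_subset, gap_one, numeric(1), beta = 10^logb))
    }
    grid_vals <- vapply(log_grid, objective, numeric(1))
    i <- which.min(grid_vals)
    lo <- log_grid[max(1, i - 1)]
    hi <- log_grid[min(length(log_grid), i + 1)]
    refine <- optimize(objective, lower = lo, upper = hi)
    if (refine$objective <= grid_vals[i]) {
      list(beta = 10^refine$minimum, value = refine$objective, grid = grid_vals)
    } else {
      list(beta = 10^log_grid[i], value = grid_vals[i], grid = grid_vals)
    }
  }

  if (per_signal) {
    fits <- purrr::map(prepped, function(p) fit_joint(list(p)))
    beta_opt <- median(vapply(fits, `[[`, numeric(1), "beta"))
    objective_value <- mean(vapply(prepped, gap_one, numeric(1), beta = beta_opt))
    grids <- purrr::map(fits, "grid")
  } else {
    fit <- fit_joint(prepped)
    beta_opt <- fit$beta
    objective_value <- fit$value
    grids <- purrr::map(prepped, function(p) {
      vapply(log_grid, function(lb) gap_one(p, 10^lb), numeric(1))
    })
  }
  trace <- dplyr::bind_rows(purrr::imap(grids, function(g, i) {
    tibble::tibble(signal = as.integer(i), beta = 10^log_grid, gap = g)
  }))
  structure(
    list(
      beta_opt = beta_opt,
      objective_value = objective_value,
      search_interval = interval,
      per_signal_gaps = trace,
      per_signal = per_signal,
      min_size = min_size
    ),
    class = "penalty_calibration"
  )
}

#' @export
print.penalty_calibration <- function(x, ...) {
  cat(sprintf(
    "<penalty_calibration: beta_opt=%.5g, mean gap=%.5g, %d signal(s)%s>\n",
    x$beta_opt, x$objective_value, length(unique(x$per_signal_gaps$signal)),
    if (x$per_signal) ", per-signal mode" else ""
  ))
  invisible(x)
}

#' @describeIn calibrate_penalty tidy method: the per-signal gap trace over
#'   the search grid.
#' @param x a `penalty_calibration`.
#' @param ... unused.
#' @export
tidy.penalty_calibration <- function(x, ...) x$per_signal_gaps

#' @describeIn calibrate_penalty glance method: one-row summary.
#' @export
glance.penalty_calibration <- function(x, ...) {
  tibble::tibble(
    beta_opt = x$beta_opt,
    objective_value = x$objective_value,
    search_lo = x$search_interval[1],
    search_hi = x$search_interval[2],
    per_signal = x$per_signal
  )
}

#' Persist / load a calibrated segmentation model
#'
#' @param calibration a `penalty_calibration`.
#' @param path JSON path.
#' @export
write_segmentation_model <- function(calibration, path) {
  jsonlite::write_json(
    list(
      beta_opt = calibration$beta_opt,
      objective_value = calibration$objective_value,
      search_interval = calibration$search_interval,
      per_signal = calibration$per_signal,
      min_size = calibration$min_size
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_segmentation_model
#' @export
read_segmentation_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      beta_opt = x$beta_opt, objective_value = x$objective_value,
      search_interval = x$search_interval,
      per_signal_gaps = tibble::tibble(
        signal = integer(), beta = numeric(), gap = numeric()
      ),
      per_signal = isTRUE(x$per_signal), min_size = x$min_size
    ),
    class = "penalty_calibration"
  )
}

#' Segment a recording end to end
#'
#' Convenience verb chaining [spectral_series()] and [pelt_segment()] and
#' returning regime spans in seconds.
#'
#' @param rec a filtered [imu_recording()].
#' @param beta penalty, or a `penalty_calibration`.
#' @param min_size minimum segment length in frames.
#' @return tibble of regimes: `regime`, `start_s`, `end_s` plus the
#'   breakpoint times as attribute `changepoints_s`.
#' @export
segment_recording <- function(rec, beta, min_size = 2) {
  if (inherits(beta, "penalty_calibration")) {
    min_size <- beta$min_size
    beta <- beta$beta_opt
  }
  sp <- spectral_series(rec)
  seg <- pelt_segment(sp, beta, min_size)
  cps <- frames_to_seconds(seg, sp)
  out <- slice_regimes(rec, cps)
  attr(out, "changepoints_s") <- cps
  out
}
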