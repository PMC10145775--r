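#' Run the full gait-analysis pipeline on one recording
#'
#' Chains the pipeline stages: bandpass filtering, spectral representation,
#' penalized change-point segmentation at the calibrated penalty, cascade
#' classification of the segmented regimes, gait criteria on the walking
#' regimes, scoring against the healthy model, and the annular summary
#' specification.
#'
#' @param rec a raw [imu_recording()].
#' @param beta penalty or `penalty_calibration`.
#' @param classifier a fitted `gait_classifier`.
#' @param healthy_model a fitted `healthy_model`.
#' @param filter_band bandpass edges in Hz.
#' @return a list of class `gait_analysis`: `regimes` (labeled spans),
#'   `criteria`, `scores`, `summary` (a `gait_summary`), and
#'   `changepoints_s`.
#' @export
analyze_recording <- function(rec, beta, classifier, healthy_model,
                              filter_band = c(0.5, 5)) {
  filtered <- bandpass(rec, filter_band[1], filter_band[2])
  regimes <- segment_recording(filtered, beta)
  changepoints_s <- attr(regimes, "changepoints_s")
  regimes <- classify_regimes(filtered, regimes, classifier)
  walking <- regimes[regimes$label == "walking", ]
  criteria <- if (nrow(walking) > 0) {
    gait_criteria(filtered, walking)
  } else {
    NULL
  }
  scores <- if (!is.null(criteria)) {
    score_regimes(criteria, healthy_model)
  } else {
    tibble::tibble(
      regime = integer(), criterion = character(), value = numeric(),
      z = numeric(), oriented_z = numeric(),
      bin = factor(character(), levels = display_bins(), ordered = TRUE)
    )
  }
  structure(
    list(
      regimes = regimes, criteria = criteria, scores = scores,
      summary = build_summary(regimes, scores),
      changepoints_s = changepoints_s
    ),
    class = "gait_analysis"
  )
}

#' @export
print.gait_analysis <- function(x, ...) {
  counts <- table(x$regimes$label)
  cat(sprintf(
    "<gait_analysis: %d regimes (%s), %d changepoints>\n",
    nrow(x$regimes),
    paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
    length(x$changepoints_s)
  ))
  invisible(x)
}

#' @describeIn analyze_recording glance method: one-row pipeline summary.
#' @param x a `gait_analysis`.
#' @param ... unused.
#' @export
glance.gait_analysis <- function(x, ...) {
  tibble::tibble(
    n_regimes = nrow(x$regimes),
    n_walking = sum(x$regimes$label == "walking"),
    n_changepoints = length(x$changepoints_s),
    walking_time_s = sum(
      (x$regimes$end_s - x$regimes$start_s)[x$regimes$label == "walking"]
    )
  )
}
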