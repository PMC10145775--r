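#' IMU recording container
#'
#' An `imu_recording` is a tibble with one row per sample and columns
#' `time_s`, `acc_cc`, `acc_ml`, `acc_ap` (accelerations, g) and `gyr_cc`,
#' `gyr_ml`, `gyr_ap` (angular velocities, deg/s), expressed on the anatomical
#' axes: craniocaudal (CC, head-to-foot), mediolateral (ML, left-right) and
#' anteroposterior (AP, front-back). The sampling rate is carried in the
#' `sampling_rate_hz` attribute and can always be re-inferred from `time_s`.
#'
#' @param data data frame with the seven columns above.
#' @param sampling_rate_hz sampling rate in Hz; inferred from `time_s` when
#'   missing.
#' @return a tibble of class `imu_recording`.
#' @export
imu_recording <- function(data, sampling_rate_hz = NULL) {
  cols <- imu_channels()
  missing_cols <- setdiff(c("time_s", cols), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data[, c("time_s", cols)])
  if (is.null(sampling_rate_hz)) {
    sampling_rate_hz <- infer_rate(data$time_s)
  }
  stopifnot(sampling_rate_hz > 0)
  structure(data,
    sampling_rate_hz = sampling_rate_hz,
    class = c("imu_recording", class(tibble::tibble()))
  )
}

imu_channels <- function() {
  c("acc_cc", "acc_ml", "acc_ap", "gyr_cc", "gyr_ml", "gyr_ap")
}

#' Sampling rate of a recording
#'
#' Reads the `sampling_rate_hz` attribute, falling back to the median time
#' step of `time_s` (so rate survives dplyr verbs that drop attributes).
#'
#' @param rec an [imu_recording()] or any data frame with a `time_s` column.
#' @return sampling rate in Hz.
#' @export
imu_rate <- function(rec) {
  fs <- attr(rec, "sampling_rate_hz")
  if (!is.null(fs)) {
    return(fs)
  }
  infer_rate(rec$time_s)
}

infer_rate <- function(time_s, tol = 0.01) {
  if (length(time_s) < 2) {
    abort("need at least two samples to infer a sampling rate")
  }
  dt <- diff(time_s)
  if (any(dt <= 0)) {
    abort("time column must be strictly increasing")
  }
  step <- median(dt)
  if (max(abs(dt - step)) > tol * step) {
    abort("irregular sampling: time steps deviate by more than 1% from the median")
  }
  1 / step
}

#' Duration of a recording in seconds
#' @param rec an [imu_recording()].
#' @return duration in seconds (number of samples / rate).
#' @export
imu_duration <- function(rec) {
  nrow(rec) / imu_rate(rec)
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf(
    "<imu_recording: %d samples, %.6g Hz, %.2f s>\n",
    nrow(x), imu_rate(x), imu_duration(x)
  ))
  NextMethod()
}

# parse an axis-map entry like "x", "-y", "z" into (column index, sign)
parse_axis <- function(spec) {
  sign <- 1
  s <- spec
  if (startsWith(s, "-")) {
    sign <- -1
    s <- substring(s, 2)
  }
  if (!s %in% c("x", "y", "z")) {
    abort(sprintf("bad axis spec '%s' (want x, y, z with optional '-')", spec))
  }
  list(axis = s, sign = sign)
}

#' Read an IMU recording from CSV
#'
#' Expects columns `time_s`, `acc_x`, `acc_y`, `acc_z`, `gyr_x`, `gyr_y`,
#' `gyr_z` (device axes). `axis_map` maps device axes onto the anatomical
#' axes, with an optional sign, e.g. `c(cc = "-y", ml = "x", ap = "z")`.
#' The sampling rate is inferred from the median time step and sampling is
#' required to be regular within 1%.
#'
#' @param path CSV file path.
#' @param axis_map named character vector with entries `cc`, `ml`, `ap`.
#' @return an [imu_recording()].
#' @export
read_imu_csv <- function(path, axis_map = c(cc = "x", ml = "y", ap = "z")) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_s", paste0("acc_", c("x", "y", "z")), paste0("gyr_", c("x", "y", "z")))
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!all(c("cc", "ml", "ap") %in% names(axis_map))) {
    abort("axis_map needs entries cc, ml, ap")
  }
  out <- tibble::tibble(time_s = df$time_s)
  for (axis in c("cc", "ml", "ap")) {
    p <- parse_axis(axis_map[[axis]])
    out[[paste0("acc_", axis)]] <- p$sign * df[[paste0("acc_", p$axis)]]
    out[[paste0("gyr_", axis)]] <- p$sign * df[[paste0("gyr_", p$axis)]]
  }
  imu_recording(out)
}

#' Write an IMU recording to CSV
#'
#' Inverse of [read_imu_csv()]: anatomical channels are written back to the
#' device columns described by `axis_map`.
#'
#' @inheritParams read_imu_csv
#' @param rec an [imu_recording()].
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path, axis_map = c(cc = "x", ml = "y", ap = "z")) {
  df <- tibble::tibble(time_s = rec$time_s)
  cols <- list()
  for (axis in c("cc", "ml", "ap")) {
    p <- parse_axis(axis_map[[axis]])
    cols[[paste0("acc_", p$axis)]] <- p$sign * rec[[paste0("acc_", axis)]]
    cols[[paste0("gyr_", p$axis)]] <- p$sign * rec[[paste0("gyr_", axis)]]
  }
  ord <- c(paste0("acc_", c("x", "y", "z")), paste0("gyr_", c("x", "y", "z")))
  df <- dplyr::bind_cols(df, tibble::as_tibble(cols)[, ord])
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write protocol annotations
#'
#' Annotations pair a recording with its ground-truth changepoints (seconds)
#' and per-regime labels (`walking`, `non_sedentary`, `sedentary`), stored as
#' JSON: `{"changepoints_s": [...], "labels": [...], "subject_id": ...,
#' "healthy": ...}`.
#'
#' @param path JSON file path.
#' @return a list with elements `changepoints_s`, `labels`, `subject_id`,
#'   `healthy`.
#' @export
read_annotation_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$changepoints_s <- as.numeric(x$changepoints_s)
  if (length(x$labels) != length(x$changepoints_s) + 1) {
    abort("annotation labels must number changepoints + 1")
  }
  x
}

#' @rdname read_annotation_json
#' @param annotation list with `changepoints_s` and `labels` (and optionally
#'   `subject_id`, `healthy`).
#' @export
write_annotation_json <- function(annotation, path) {
  stopifnot(length(annotation$labels) == length(annotation$changepoints_s) + 1)
  jsonlite::write_json(
    annotation[intersect(
      c("changepoints_s", "labels", "subject_id", "healthy"),
      names(annotation)
    )],
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
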