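#' Match predicted to true changepoints within a temporal margin
#'
#' One-to-one greedy matching over increasing absolute time difference: each
#' true and each predicted changepoint is used at most once, and a pair
#' counts only if its time difference is at most `margin_s`.
#'
#' @param true_s,pred_s sorted changepoint times in seconds (possibly empty).
#' @param margin_s matching margin in seconds (default 3.5; it should not
#'   exceed the minimum spacing between true changepoints).
#' @return integer count of true positives.
#' @export
match_changepoints <- function(true_s, pred_s, margin_s = 3.5) {
  if (length(true_s) == 0 || length(pred_s) == 0) {
    return(0L)
  }
  d <- abs(outer(true_s, pred_s, "-"))
  pairs <- which(d <= margin_s, arr.ind = TRUE)
  if (nrow(pairs) == 0) {
    return(0L)
  }
  pairs <- pairs[order(d[pairs]), , drop = FALSE]
  used_t <- logical(length(true_s))
  used_p <- logical(length(pred_s))
  tp <- 0L
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]
    j <- pairs[r, 2]
    if (!used_t[i] && !used_p[j]) {
      used_t[i] <- TRUE
      used_p[j] <- TRUE
      tp <- tp + 1L
    }
  }
  tp
}

#' Margin-based segmentation metrics
#'
#' Precision = TP / K (predicted count), recall = TP / K* (true count), and
#' their harmonic mean F1, with TP from [match_changepoints()]. An empty
#' prediction against a non-empty truth scores precision 0 (not NaN); two
#' empty sets score a perfect 1.
#'
#' @inheritParams match_changepoints
#' @return one-row tibble: `tp`, `k_pred`, `k_true`, `precision`, `recall`,
#'   `f1`, `margin_s`.
#' @export
segmentation_report <- function(true_s, pred_s, margin_s = 3.5) {
  tp <- match_changepoints(true_s, pred_s, margin_s)
  k <- length(pred_s)
  k_star <- length(true_s)
  if (k == 0 && k_star == 0) {
    precision <- recall <- f1 <- 1
  } else {
    precision <- if (k == 0) 0 else tp / k
    recall <- if (k_star == 0) 0 else tp / k_star
    f1 <- if (precision + recall == 0) {
      0
    } else {
      2 * precision * recall / (precision + recall)
    }
  }
  tibble::tibble(
    tp = tp, k_pred = k, k_true = k_star,
    precision = precision, recall = recall, f1 = f1, margin_s = margin_s
  )
}

#' Per-sample labels induced by labeled regimes
#'
#' @param regimes tibble with `start_s`, `end_s`, `label`.
#' @param times sample times in seconds.
#' @return character vector, one label per time.
#' @export
labels_at_samples <- function(regimes, times) {
  idx <- findInterval(times, c(regimes$start_s, regimes$end_s[nrow(regimes)]),
    rightmost.closed = TRUE
  )
  idx <- pmin(pmax(idx, 1L), nrow(regimes))
  regimes$label[idx]
}

#' Sample-scale confusion matrix
#'
#' Row-normalized percentages: entry (r, c) is the percentage of samples
#' annotated as class r that were classified as class c, over the classes
#' walking, non_sedentary, sedentary.
#'
#' @param true_labels,pred_labels equal-length per-sample label vectors.
#' @return a 3 x 3 matrix of class `gait_confusion` (percentages; raw counts
#'   in attribute `counts`).
#' @export
sample_confusion <- function(true_labels, pred_labels) {
  cls <- c("walking", "non_sedentary", "sedentary")
  if (length(true_labels) != length(pred_labels)) {
    abort("label sequences must have equal length")
  }
  if (!all(c(true_labels, pred_labels) %in% cls)) {
    abort("labels must be walking, non_sedentary or sedentary")
  }
  counts <- table(
    factor(true_labels, levels = cls),
    factor(pred_labels, levels = cls)
  )
  counts <- matrix(as.numeric(counts), 3, 3, dimnames = list(cls, cls))
  pct <- counts
  for (r in 1:3) {
    rs <- sum(counts[r, ])
    pct[r, ] <- if (rs > 0) 100 * counts[r, ] / rs else 0
  }
  structure(pct, counts = counts, class = c("gait_confusion", "matrix", "array"))
}

#' @export
print.gait_confusion <- function(x, ...) {
  cat("<sample-scale confusion matrix, row percentages>\n")
  print(round(unclass(x), 2))
  invisible(x)
}

#' @rdname sample_confusion
#' @param x a `gait_confusion`.
#' @param ... unused.
#' @return for `tidy()`: long tibble `truth`, `prediction`, `percent`,
#'   `count`.
#' @export
tidy.gait_confusion <- function(x, ...) {
  cls <- rownames(x)
  counts <- attr(x, "counts")
  tibble::tibble(
    truth = rep(cls, times = 3),
    prediction = rep(cls, each = 3),
    percent = as.numeric(unclass(x)),
    count = as.numeric(counts)
  )
}

#' Subject-wise cross-validation folds balanced on health status
#'
#' Subjects are shuffled within the healthy and pathological groups and dealt
#' round-robin, so each fold is subject-disjoint and carries the same healthy
#' / pathological proportions (e.g. 21 healthy + 9 pathological over 3 folds
#' gives 7 + 3 per fold).
#'
#' @param subjects tibble with `subject_id` and logical `healthy`.
#' @param n_folds number of folds (default 3).
#' @param seed integer seed for the shuffle.
#' @return `subjects` with an integer `fold` column.
#' @export
crossval_splits <- function(subjects, n_folds = 3, seed = 1) {
  stopifnot(all(c("subject_id", "healthy") %in% names(subjects)))
  if (nrow(subjects) < n_folds) {
    abort("fewer subjects than folds")
  }
  set.seed(seed)
  fold <- integer(nrow(subjects))
  for (grp in unique(subjects$healthy)) {
    idx <- which(subjects$healthy == grp)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  dplyr::mutate(subjects, fold = fold)
}

#' The ten degraded feature-computation windows of one regime
#'
#' Sub-spans used by the robustness study: the full regime; its first 3,
#' 3.5, 4 and 5 s; its first 40%; 40% windows starting at 20%, 30% and 40%
#' of the duration; and its last 40%. Absolute prefixes are clipped (with a
#' warning) when the regime is shorter than 5 s.
#'
#' @param start_s,end_s the regime span in seconds.
#' @return tibble with `config`, `start_s`, `end_s` (10 rows).
#' @export
degraded_ranges <- function(start_s, end_s) {
  dur <- end_s - start_s
  stopifnot(dur > 0)
  if (dur < 5) {
    warn("regime shorter than 5 s: absolute-prefix windows clipped")
  }
  pre <- function(s) c(start_s, min(start_s + s, end_s))
  frac <- function(from, len) {
    c(start_s + from * dur, start_s + (from + len) * dur)
  }
  spans <- rbind(
    c(start_s, end_s),
    pre(3), pre(3.5), pre(4), pre(5),
    frac(0, 0.4), frac(0.2, 0.4), frac(0.3, 0.4), frac(0.4, 0.4),
    frac(0.6, 0.4)
  )
  tibble::tibble(
    config = c(
      "full", "first_3s", "first_3.5s", "first_4s", "first_5s",
      "first_40pct", "40pct_at_20pct", "40pct_at_30pct", "40pct_at_40pct",
      "last_40pct"
    ),
    start_s = spans[, 1], end_s = spans[, 2]
  )
}

#' Robustness of the gait criteria to degraded segmentation
#'
#' Recomputes the four criteria of each walking regime on the ten degraded
#' windows of [degraded_ranges()] and summarizes their spread.
#'
#' @param rec a filtered [imu_recording()].
#' @param regimes tibble of walking regimes (`regime`, `start_s`, `end_s`).
#' @return list with `values` (long tibble: regime, config, criterion,
#'   value) and `summary` (per regime x criterion: median, IQR, and the
#'   full-window value).
#' @export
robustness_report <- function(rec, regimes) {
  values <- dplyr::bind_rows(purrr::map(seq_len(nrow(regimes)), function(i) {
    spans <- degraded_ranges(regimes$start_s[i], regimes$end_s[i])
    crit <- gait_criteria(rec, spans)
    long <- tidyr::pivot_longer(
      crit[, c("config", criterion_names())],
      cols = dplyr::all_of(criterion_names()),
      names_to = "criterion", values_to = "value"
    )
    dplyr::mutate(long, regime = regimes$regime[i], .before = 1)
  }))
  summary <- dplyr::summarise(
    dplyr::group_by(values, .data$regime, .data$criterion),
    median = median(.data$value),
    iqr = stats::IQR(.data$value),
    full_value = .data$value[.data$config == "full"],
    .groups = "drop"
  )
  list(values = values, summary = summary)
}
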