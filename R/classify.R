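# extract a linear decision function (w, b) from a fitted two-class
# e1071::svm with linear kernel, oriented so that decision > 0 predicts
# `positive`
linear_svm <- function(x, y, positive, cost = 1) {
  y <- factor(y)
  if (nlevels(y) < 2) {
    abort("classifier stage needs two classes present in training data")
  }
  fit <- e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  pred <- predict(fit, x)
  dec <- as.numeric(x %*% w + b)
  # align the sign convention with the fitted model's own predictions
  agree <- mean((dec > 0) == (pred == positive))
  if (agree < 0.5) {
    w <- -w
    b <- -b
  }
  negative <- setdiff(levels(y), positive)
  list(w = w, b = b, positive = positive, negative = negative)
}

linear_decide <- function(clf, x) {
  dec <- as.numeric(x %*% clf$w + clf$b)
  ifelse(dec > 0, clf$positive, clf$negative)
}

#' Fit the cascade regime classifier
#'
#' Standardizes the features, projects them onto the smallest set of
#' principal components retaining at least 99% of the cumulative explained
#' variance (fitted on the training regimes only), then trains two
#' soft-margin linear support-vector machines in cascade: stage 1 separates
#' walking from non-walking on all regimes, stage 2 separates sedentary from
#' non-sedentary on the non-walking training regimes only.
#'
#' @param features tibble of regime features (e.g. from
#'   [features_for_regimes()]); non-feature columns `regime`, `start_s`,
#'   `end_s`, `label` are ignored.
#' @param labels character vector in `{walking, non_sedentary, sedentary}`,
#'   one per row of `features`.
#' @param variance_kept cumulative explained-variance threshold (default
#'   0.99).
#' @param cost soft-margin constant for both stages (default 1).
#' @return an object of class `gait_classifier`.
#' @export
fit_classifiers <- function(features, labels, variance_kept = 0.99, cost = 1) {
  cls <- c("walking", "non_sedentary", "sedentary")
  if (!all(labels %in% cls)) {
    abort("labels must be walking, non_sedentary or sedentary")
  }
  cols <- setdiff(feature_columns(features), "label")
  x <- as.matrix(features[, cols])
  if (nrow(x) != length(labels)) {
    abort("one label per feature row required")
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ == 0] <- 1
  z <- sweep(sweep(x, 2, center), 2, scale_, "/")
  pca <- prcomp(z, center = FALSE, scale. = FALSE)
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  k <- which(cum >= variance_kept)[1]
  rotation <- pca$rotation[, seq_len(k), drop = FALSE]
  zp <- z %*% rotation
  stage1 <- linear_svm(
    zp, ifelse(labels == "walking", "walking", "non_walking"),
    positive = "walking", cost = cost
  )
  nw <- labels != "walking"
  if (length(unique(labels[nw])) < 2) {
    abort("stage 2 needs both sedentary and non_sedentary training regimes")
  }
  stage2 <- linear_svm(
    zp[nw, , drop = FALSE], labels[nw],
    positive = "non_sedentary", cost = cost
  )
  structure(
    list(
      feature_names = cols, center = center, scale = scale_,
      rotation = rotation, n_components = k,
      variance_kept = cum[k], stage1 = stage1, stage2 = stage2
    ),
    class = "gait_classifier"
  )
}

#' Predict regime labels with the cascade
#'
#' Stage 1 decides walking vs non-walking; regimes predicted walking never
#' reach stage 2, which splits the remainder into sedentary vs
#' non-sedentary.
#'
#' @param model a fitted `gait_classifier`.
#' @param features tibble or matrix with the model's feature columns.
#' @return character vector of labels.
#' @export
predict_labels <- function(model, features) {
  if (is.data.frame(features)) {
    missing_cols <- setdiff(model$feature_names, names(features))
    if (length(missing_cols) > 0) {
      abort(paste0("missing feature column(s): ", paste(missing_cols, collapse = ", ")))
    }
    x <- as.matrix(features[, model$feature_names])
  } else {
    if (ncol(features) != length(model$feature_names)) {
      abort("feature matrix width does not match the fitted model")
    }
    x <- features
  }
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  zp <- z %*% model$rotation
  out <- linear_decide(model$stage1, zp)
  nw <- out != "walking"
  if (any(nw)) {
    out[nw] <- linear_decide(model$stage2, zp[nw, , drop = FALSE])
  }
  out
}

#' Classify regimes of a recording
#'
#' Regimes shorter than one second (possible since the solver's minimum
#' segment length is 0.2 s) have their feature window symmetrically widened
#' to 1 s of context, clipped to the recording; the reported span is
#' unchanged.
#'
#' @param rec a filtered [imu_recording()].
#' @param regimes tibble with `start_s`, `end_s`.
#' @param model a fitted `gait_classifier`.
#' @return `regimes` with a `label` column appended.
#' @export
classify_regimes <- function(rec, regimes, model) {
  t0 <- rec$time_s[1]
  t1 <- t0 + imu_duration(rec)
  windows <- dplyr::mutate(regimes,
    pad = pmax(0, 1.001 - (.data$end_s - .data$start_s)) / 2,
    start_s = pmax(t0, .data$start_s - .data$pad),
    end_s = pmin(t1, .data$end_s + .data$pad)
  )
  feats <- features_for_regimes(rec, windows[, c("start_s", "end_s")])
  dplyr::mutate(regimes, label = predict_labels(model, feats))
}

#' @export
print.gait_classifier <- function(x, ...) {
  cat(sprintf(
    "<gait_classifier: %d features -> %d components (%.1f%% variance), linear SVM cascade>\n",
    length(x$feature_names), x$n_components, 100 * x$variance_kept
  ))
  invisible(x)
}

#' @describeIn fit_classifiers glance method: one-row summary.
#' @param x a `gait_classifier`.
#' @param ... unused.
#' @export
glance.gait_classifier <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$feature_names),
    n_components = x$n_components,
    variance_kept = x$variance_kept
  )
}

#' Persist / load the cascade classifier as JSON
#'
#' Stores the standardization, projection and linear stage weights; the
#' loaded model predicts identically to the fitted one.
#'
#' @param model a `gait_classifier`.
#' @param path JSON path.
#' @export
write_classifier <- function(model, path) {
  jsonlite::write_json(
    list(
      feature_names = model$feature_names,
      center = as.numeric(model$center),
      scale = as.numeric(model$scale),
      rotation = model$rotation,
      n_components = model$n_components,
      variance_kept = model$variance_kept,
      stage1 = model$stage1, stage2 = model$stage2
    ),
    path,
    digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rotation <- x$rotation
  if (!is.matrix(rotation)) rotation <- as.matrix(rotation)
  structure(
    list(
      feature_names = x$feature_names,
      center = stats::setNames(as.numeric(x$center), x$feature_names),
      scale = stats::setNames(as.numeric(x$scale), x$feature_names),
      rotation = rotation, n_components = x$n_components,
      variance_kept = x$variance_kept,
      stage1 = x$stage1, stage2 = x$stage2
    ),
    class = "gait_classifier"
  )
}
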