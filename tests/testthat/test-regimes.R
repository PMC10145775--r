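test_that("regime slicing covers the recording exactly once", {
  rec <- tone_recording(2, duration_s = 30)
  one <- slice_regimes(rec, numeric(0))
  expect_equal(nrow(one), 1)
  expect_equal(c(one$start_s, one$end_s), c(0, 30))
  three <- slice_regimes(rec, c(10, 20))
  expect_equal(three$start_s, c(0, 10, 20))
  expect_equal(three$end_s, c(10, 20, 30))
  covered <- sum(vapply(seq_len(3), function(i) {
    nrow(regime_samples(rec, three$start_s[i], three$end_s[i]))
  }, numeric(1)))
  expect_equal(covered, nrow(rec))
  expect_error(slice_regimes(rec, c(10, 40)), "interior")
})

test_that("nearest-rank percentiles follow the rank formula", {
  expect_equal(gaitview:::percentile_rank(c(1, 2, 3, 4), 75), 3)
  expect_equal(gaitview:::percentile_rank(c(1, 2, 3, 4), 25), 1)
  expect_equal(gaitview:::percentile_rank(c(4, 1, 3, 2), 75), 3) # sorts first
  expect_equal(gaitview:::percentile_rank(c(1, 2, 3, 4), 5), 1) # rank floor 1
  expect_equal(gaitview:::percentile_rank(1:10, 85), 9) # ceil(8.5)
})

test_that("features of a constant channel degrade gracefully", {
  rec <- tone_recording(2, duration_s = 10, channel = "acc_ap")
  rec$acc_ml <- rep(0.5, nrow(rec))
  f <- extract_features(rec, 0, 10)
  expect_length(f, 129)
  expect_equal(unname(f["mean_acc_ml"]), 0.5)
  expect_equal(unname(f["std_acc_ml"]), 0)
  expect_equal(unname(f["min_acc_ml"]), 0.5)
  expect_equal(unname(f["max_acc_ml"]), 0.5)
  expect_equal(unname(f["rms_acc_ml"]), 0.5)
  expect_equal(unname(f["cv_acc_ml"]), 0) # sd/mean well-defined but 0
  expect_true(all(is.finite(f)))
  expect_error(extract_features(rec, 0, 0.5), "too short")
})

test_that("dominant-frequency features match a periodogram oracle", {
  rec <- tone_recording(2, duration_s = 10, channel = "acc_ap")
  rec$acc_ap <- rec$acc_ap + 0.4 * sin(2 * pi * 3.4 * rec$time_s)
  f <- extract_features(rec, 0, 10)
  expect_lt(abs(f[["f0_acc_ap"]] - 2), 0.1 + 1e-9) # one bin at 10 s
  expect_lt(abs(f[["f2_acc_ap"]] - 3.4), 0.1 + 1e-9)
  expect_gt(f[["pd0_acc_ap"]], f[["pd2_acc_ap"]])
})

test_that("features are stable under small crops of a stationary regime", {
  set.seed(1)
  kn <- gait_knobs(
    step_freq_hz = 2, asymmetry_delta = 0,
    timing_jitter_sd = 0, noise_sd = 0
  )
  rec <- block_to_recording(generate_walking_segment(kn, 30, 100))
  full <- extract_features(rec, 0, 30)
  cropped <- extract_features(rec, 1.5, 28.5) # 5% off both ends
  # periodogram *power* features scale with segment length by construction;
  # the n-1 denominator of sd/var admits O(1/n) shifts under cropping
  keep <- setdiff(names(full), grep("^pd", names(full), value = TRUE))
  expect_equal(full[keep], cropped[keep], tolerance = 1e-4)
})

test_that("feature ordering is fixed and tabulation matches single calls", {
  ar <- generate_protocol(quick_config(), seed = 13)
  rec <- bandpass(ar$recording)
  tab <- features_for_regimes(rec, ar$regimes)
  expect_equal(nrow(tab), nrow(ar$regimes))
  f1 <- extract_features(rec, ar$regimes$start_s[2], ar$regimes$end_s[2])
  expect_equal(unlist(tab[2, names(f1)]), f1)
})

test_that("the cascade separates synthetic clouds and conserves regimes", {
  set.seed(2)
  n <- 40
  mk <- function(mu) {
    tibble::tibble(
      a = rnorm(n, mu[1], 0.2), b = rnorm(n, mu[2], 0.2),
      c = rnorm(n, mu[3], 0.2), d = rnorm(n, 0, 0.2)
    )
  }
  feats <- dplyr::bind_rows(mk(c(5, 0, 0)), mk(c(0, 5, 0)), mk(c(0, 0, 5)))
  labels <- rep(c("walking", "non_sedentary", "sedentary"), each = n)
  m <- fit_classifiers(feats, labels)
  pred <- predict_labels(m, feats)
  expect_equal(mean(pred == labels), 1)
  # cascade conservation: every regime gets exactly one of the three labels
  expect_equal(sort(unique(pred)), sort(unique(labels)))
  expect_equal(length(pred), nrow(feats))
  # determinism
  expect_identical(pred, predict_labels(m, feats))
})

test_that("the projection keeps the smallest 99%-variance component set", {
  set.seed(3)
  x <- matrix(rnorm(200 * 6), 200, 6) %*% diag(c(10, 5, 2, 0.5, 0.1, 0.01))
  feats <- tibble::as_tibble(as.data.frame(x))
  labels <- rep(c("walking", "non_sedentary", "sedentary"), length.out = 200)
  m <- fit_classifiers(feats, labels)
  z <- scale(x)
  ev <- eigen(stats::cov(z), symmetric = TRUE, only.values = TRUE)$values
  k_oracle <- which(cumsum(ev) / sum(ev) >= 0.99)[1]
  expect_equal(m$n_components, k_oracle)
  expect_gte(m$variance_kept, 0.99)
})

test_that("degenerate training sets are rejected", {
  feats <- tibble::tibble(a = rnorm(20), b = rnorm(20))
  expect_error(
    fit_classifiers(feats, rep("walking", 20)),
    "two classes"
  )
  expect_error(
    fit_classifiers(feats, rep(c("walking", "sedentary"), 10)),
    "stage 2"
  )
  expect_error(
    fit_classifiers(feats, rep(c("walking", "resting"), 10)),
    "labels"
  )
})

test_that("classifier JSON persistence predicts identically", {
  ar <- generate_protocol(quick_config(), seed = 14)
  rec <- bandpass(ar$recording)
  feats <- features_for_regimes(rec, ar$regimes)
  m <- fit_classifiers(feats, ar$regimes$label)
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(m, path)
  back <- read_classifier(path)
  expect_identical(predict_labels(back, feats), predict_labels(m, feats))
  expect_error(
    predict_labels(m, feats[, 1:10]),
    "missing feature"
  )
})

test_that("prototype regimes from all three classes are recovered in-sample", {
  coh <- generate_cohort(4, seed = 15, config = quick_config())
  feats <- dplyr::bind_rows(lapply(coh$recording, function(ar) {
    f <- features_for_regimes(bandpass(ar$recording), ar$regimes)
    f$label <- ar$regimes$label
    f
  }))
  m <- fit_classifiers(dplyr::select(feats, -label), feats$label)
  pred <- predict_labels(m, feats)
  expect_gte(mean(pred == feats$label), 0.95)
  # regimes predicted walking by stage 1 keep the walking label (cascade)
  expect_true(all(pred %in% c("walking", "non_sedentary", "sedentary")))
})
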