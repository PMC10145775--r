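test_that("segment cost matches hand arithmetic and a naive oracle", {
  expect_equal(segment_cost(rep(3, 10), 0, 10), 0)
  expect_equal(segment_cost(c(0, 0, 4, 4), 0, 4), 16) # mean 2, 4 * 2^2
  set.seed(1)
  m <- matrix(rnorm(50 * 3), 50, 3)
  for (i in 1:20) {
    ab <- sort(sample(0:50, 2))
    if (ab[1] == ab[2]) next
    expect_equal(
      segment_cost(m, ab[1], ab[2]),
      naive_cost(m, ab[1], ab[2]),
      tolerance = 1e-9
    )
  }
  expect_error(segment_cost(m, 5, 5), "empty")
})

test_that("penalized risk follows the cost-plus-penalty decomposition", {
  y <- c(0, 0, 0, 4, 4, 4)
  expect_equal(penalized_risk(y, integer(0), 1), 24)
  expect_equal(penalized_risk(y, 3L, 1), 1)
  expect_equal(penalized_risk(rep(1, 8), integer(0), 2), 0)
  # residual-free piecewise-constant signal: risk is exactly beta * K
  z <- rep(c(1, -2, 5), each = 10)
  expect_equal(penalized_risk(z, c(10L, 20L), 7), 14)
  expect_error(penalized_risk(y, c(4L, 2L), 1), "increasing")
})

test_that("PELT solves the toy cases exactly", {
  y <- c(0, 0, 0, 4, 4, 4)
  expect_equal(pelt_segment(y, beta = 1)$breakpoints, 3L)
  expect_equal(pelt_segment(y, beta = 30)$breakpoints, integer(0))
  expect_equal(pelt_segment(rep(2, 30), beta = 0.5)$breakpoints, integer(0))
  expect_error(pelt_segment(y, beta = 1, min_size = 4), "too short")
})

test_that("PELT attains the brute-force optimum on random instances", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(30:60, 1)
    d <- sample(c(1, 4), 1)
    y <- piecewise_signal(
      n = n, d = d,
      breaks = sort(sample(seq(5, n - 5), sample(0:3, 1))),
      jump = runif(1, 0.5, 4), noise = runif(1, 0.05, 1)
    )
    beta <- 10^runif(1, -2, 2)
    a <- pelt_segment(y, beta)
    b <- brute_force_segment(y, beta)
    expect_equal(a$risk, b$risk, tolerance = 1e-9)
    expect_equal(a$breakpoints, b$breakpoints)
  }
})

test_that("detected breakpoint count is non-increasing in the penalty", {
  set.seed(9)
  y <- piecewise_signal(n = 150, d = 2, breaks = c(40, 75, 110))
  ks <- vapply(
    10^seq(-2, 3, length.out = 12),
    function(b) length(pelt_segment(y, b)$breakpoints),
    numeric(1)
  )
  expect_true(all(diff(ks) <= 0))
})

test_that("adding a breakpoint never increases the unpenalized risk", {
  set.seed(10)
  y <- piecewise_signal(n = 80, d = 2, breaks = c(30, 55))
  eps <- 1e-6 # tiny beta ~ unpenalized
  for (i in 1:10) {
    bp <- sort(sample(2:78, 3))
    with_bp <- penalized_risk(y, bp, eps)
    extra <- sample(setdiff(2:78, c(bp, bp + 1, bp - 1)), 1)
    with_more <- penalized_risk(y, sort(c(bp, extra)), eps)
    expect_lte(with_more - eps, with_bp)
  }
})

test_that("minimum segment length is honored and the limit case collapses", {
  set.seed(11)
  y <- rnorm(40)
  seg <- pelt_segment(y, beta = 0.01, min_size = 5)
  lens <- diff(c(0, seg$breakpoints, 40))
  expect_true(all(lens >= 5))
  tiny <- brute_force_segment(y, beta = 1e-9, min_size = 1)
  expect_equal(tiny$risk, 0, tolerance = 1e-6)
  expect_error(brute_force_segment(matrix(0, 2001, 1), 1), "guarded")
})

test_that("frame/second conversions follow the frame-center convention", {
  ar <- generate_protocol(quick_config(), seed = 8)
  sp <- spectral_series(bandpass(ar$recording))
  expect_equal(frames_to_seconds(100L, sp), 100 * 0.1 + 1.5)
  secs <- c(12.34, 40.01, 61.97)
  back <- frames_to_seconds(seconds_to_frames(secs, sp), sp)
  expect_true(all(abs(back - secs) <= 0.05 + 1e-9))
  # interior clamping: never emits frame 0 or n
  expect_gte(min(seconds_to_frames(0, sp)), 1)
  expect_lte(max(seconds_to_frames(1e4, sp)), nrow(sp$frames) - 1)
})

test_that("tidy and glance summarize segmentations", {
  y <- rep(c(0, 6), each = 20)
  seg <- pelt_segment(y, beta = 2)
  td <- tidy(seg)
  expect_equal(td$start_frame, c(0L, 20L))
  expect_equal(td$end_frame, c(20L, 40L))
  g <- glance(seg)
  expect_equal(g$n_breakpoints, 1)
  expect_equal(g$risk, 2, tolerance = 1e-9)
})

test_that("penalty calibration recovers a zero-gap interval when truth is optimal", {
  set.seed(3)
  y <- piecewise_signal(
    n = 150, d = 3, breaks = c(50, 100),
    jump = 10, noise = 0.05
  )
  cal <- calibrate_penalty(list(list(spectral = y, breakpoints = c(50L, 100L))))
  expect_gt(cal$beta_opt, 0)
  expect_lt(cal$objective_value, 1e-6)
  # the solver at the calibrated penalty reproduces the annotation
  expect_equal(
    pelt_segment(y, cal$beta_opt)$breakpoints, c(50L, 100L)
  )
  # excess risk is non-negative along the whole trace (solver optimality)
  expect_true(all(tidy(cal)$gap >= -1e-8))
})

test_that("calibrated penalties generalize to held-out piecewise signals", {
  make <- function(seed) {
    set.seed(seed)
    breaks <- sort(sample(seq(30, 170, by = 20), 3))
    list(
      spectral = piecewise_signal(
        n = 200, d = 3, breaks = breaks,
        jump = 5, noise = 0.2
      ),
      breakpoints = as.integer(breaks)
    )
  }
  train <- lapply(1:5, make)
  cal <- calibrate_penalty(train)
  f1 <- vapply(6:15, function(seed) {
    te <- make(seed)
    pred <- pelt_segment(te$spectral, cal$beta_opt)$breakpoints
    segmentation_report(te$breakpoints, pred, margin_s = 2)$f1
  }, numeric(1))
  expect_equal(mean(f1), 1)
  # per-signal mode agrees on scale
  cal2 <- calibrate_penalty(train, per_signal = TRUE)
  expect_gt(cal2$beta_opt, cal$beta_opt / 50)
  expect_lt(cal2$beta_opt, cal$beta_opt * 50)
})

test_that("calibration model persistence round-trips", {
  set.seed(5)
  y <- piecewise_signal(n = 100, d = 2, breaks = 50L, jump = 8, noise = 0.1)
  cal <- calibrate_penalty(list(list(spectral = y, breakpoints = 50L)))
  path <- withr::local_tempfile(fileext = ".json")
  write_segmentation_model(cal, path)
  back <- read_segmentation_model(path)
  expect_equal(back$beta_opt, cal$beta_opt, tolerance = 1e-12)
  expect_equal(back$min_size, cal$min_size)
})
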