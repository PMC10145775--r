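test_that("RMS ratios satisfy symmetry cases and the Pythagorean identity", {
  n <- 200
  x <- rnorm(n)
  same <- tibble::tibble(acc_cc = x, acc_ml = x, acc_ap = x)
  rr <- rms_ratios(same)
  expect_equal(rr$rmsr_ml, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(rr$rmsr_ap, 1 / sqrt(3), tolerance = 1e-12)
  ml_only <- tibble::tibble(
    acc_cc = numeric(n), acc_ml = rnorm(n), acc_ap = numeric(n)
  )
  rr2 <- rms_ratios(ml_only)
  expect_equal(rr2$rmsr_ml, 1)
  expect_equal(rr2$rmsr_ap, 0)
  set.seed(1)
  for (i in 1:50) {
    df <- tibble::tibble(
      acc_cc = rnorm(50, sd = runif(1, 0.1, 3)),
      acc_ml = rnorm(50, sd = runif(1, 0.1, 3)),
      acc_ap = rnorm(50, sd = runif(1, 0.1, 3))
    )
    r <- rms_ratios(df)
    expect_equal(r$rmsr_ml^2 + r$rmsr_ap^2 + r$rmsr_cc^2, 1, tolerance = 1e-12)
  }
  expect_error(
    rms_ratios(tibble::tibble(
      acc_cc = numeric(5), acc_ml = numeric(5), acc_ap = numeric(5)
    )),
    "all-zero"
  )
})

test_that("unbiased autocorrelation matches the naive oracle", {
  set.seed(2)
  x <- rnorm(500)
  expect_equal(autocorrelation_unbiased(x), naive_acf_unbiased(x),
    tolerance = 1e-8
  )
  expect_equal(autocorrelation_unbiased(x)[1], 1)
  # cosine case: 1 s period sampled at 100 Hz for 30 s
  t <- (0:2999) / 100
  acf <- autocorrelation_unbiased(sin(2 * pi * t))
  expect_gte(acf[101], 0.99)
  expect_gt(acf[101], acf[96])
  expect_gt(acf[101], acf[106])
  expect_error(autocorrelation_unbiased(rep(2, 100)), "zero-variance")
  expect_error(autocorrelation_unbiased(rnorm(4)), "too short")
})

test_that("peak extraction separates step and stride structure", {
  t <- (0:2999) / 100
  fs <- 100
  # symmetric gait: equal one-step and two-step peaks
  sym <- sin(2 * pi * 2 * t) + 0.3 * sin(2 * pi * 4 * t)
  pk <- acf_peaks(autocorrelation_unbiased(sym), 2, fs)
  expect_lt(abs(pk$p1 - pk$p2), 0.01)
  # strong stride admixture: one-step peak drops, two-step peak stays
  asym <- sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 1 * t)
  pk2 <- acf_peaks(autocorrelation_unbiased(asym), 2, fs)
  expect_lt(pk2$p1, pk$p1 - 0.1)
  expect_gt(pk2$p2, 0.95)
  # pure stride-periodic signal: no step-lag structure at all — the search
  # window's best value sits at the cosine zero crossing, far below the
  # stride peak
  stride <- sin(2 * pi * 1 * t)
  pk3 <- acf_peaks(autocorrelation_unbiased(stride), 2, fs)
  expect_lt(pk3$p1, 0.05)
  expect_gt(pk3$p2, 0.95)
  expect_error(
    acf_peaks(autocorrelation_unbiased(sym[1:100]), 2, fs),
    "outside ACF support"
  )
})

test_that("criteria computed through the pipeline respond to the knobs", {
  crit_of <- function(knobs, seed) {
    ar <- generate_protocol(quick_config(), knobs, seed = seed)
    cr <- gait_criteria(
      bandpass(ar$recording),
      ar$regimes[ar$regimes$label == "walking", ]
    )
    colMeans(cr[c("rmsr_ml", "rmsr_ap", "p1cc", "p2cc")])
  }
  base <- crit_of(gait_knobs(), 31)
  expect_gt(crit_of(gait_knobs(amp_ap = 0.3), 31)[["rmsr_ap"]], base[["rmsr_ap"]])
  asym <- crit_of(gait_knobs(asymmetry_delta = 0.5), 31)
  expect_lt(asym[["p1cc"]], base[["p1cc"]] - 0.1)
  expect_lt(abs(asym[["p2cc"]] - base[["p2cc"]]), 0.05)
  expect_lt(
    crit_of(gait_knobs(timing_jitter_sd = 0.06), 31)[["p2cc"]],
    base[["p2cc"]] - 0.1
  )
})

make_healthy_criteria <- function(n = 30, seed = 4) {
  set.seed(seed)
  tibble::tibble(
    regime = seq_len(n),
    rmsr_ml = rnorm(n, 0.3, 0.05),
    rmsr_ap = rnorm(n, 0.5, 0.06),
    p1cc = rnorm(n, 0.95, 0.02),
    p2cc = rnorm(n, 0.95, 0.02)
  )
}

test_that("healthy model centers, bounds and coverage behave as defined", {
  crit <- make_healthy_criteria()
  hm <- fit_healthy_model(crit)
  ref <- tidy(hm)
  expect_true(all(ref$sigma > 0))
  expect_true(all(ref$x_min < ref$x_max))
  # z of the healthy mean is 0 for every criterion
  means <- crit[1, ]
  for (cn in c("rmsr_ml", "rmsr_ap", "p1cc", "p2cc")) {
    means[[cn]] <- mean(crit[[cn]])
  }
  sc <- score_regimes(means, hm)
  expect_true(all(abs(sc$z) < 1e-12))
  expect_true(all(sc$bin == "within"))
  # ~80% of the healthy regimes fall inside the 10/90 bounds
  sc_all <- score_regimes(crit, hm)
  ref_j <- dplyr::left_join(sc_all, ref, by = "criterion")
  inside <- dplyr::summarise(
    dplyr::group_by(ref_j, criterion),
    k = sum(z >= x_min & z <= x_max)
  )
  expect_true(all(abs(inside$k - 0.8 * nrow(crit)) <= 2))
  expect_error(fit_healthy_model(crit[1:5, ]), "at least 10")
  degenerate <- crit
  degenerate$p1cc <- 0.9
  expect_error(fit_healthy_model(degenerate), "zero variance")
})

test_that("scoring is invariant to affine rescaling of a criterion", {
  crit <- make_healthy_criteria()
  hm <- fit_healthy_model(crit)
  scaled <- crit
  scaled$rmsr_ml <- 2 * scaled$rmsr_ml + 0.1
  hm2 <- fit_healthy_model(scaled)
  test_crit <- make_healthy_criteria(n = 12, seed = 9)
  test_scaled <- test_crit
  test_scaled$rmsr_ml <- 2 * test_scaled$rmsr_ml + 0.1
  s1 <- score_regimes(test_crit, hm)
  s2 <- score_regimes(test_scaled, hm2)
  expect_equal(s1$z, s2$z, tolerance = 1e-9)
  expect_identical(as.character(s1$bin), as.character(s2$bin))
})

test_that("display bins honor orientation and the half-width rule", {
  crit <- make_healthy_criteria(n = 40)
  hm <- fit_healthy_model(crit)
  ref <- tidy(hm)
  probe <- crit[1, ]
  for (cn in c("rmsr_ap", "rmsr_ml")) {
    row <- ref[ref$criterion == cn, ]
    half <- 0.5 * (row$x_max - row$x_min)
    # oriented z just below the lower display bound, by less than half-width
    z_target <- if (row$orientation > 0) {
      row$x_min - 0.4 * half
    } else {
      row$x_max + 0.4 * half # negation flips the bound
    }
    probe[[cn]] <- row$mu + row$sigma * z_target
    sc <- score_regimes(probe, hm)
    expect_equal(
      as.character(sc$bin[sc$criterion == cn]), "slightly_below"
    )
    # well beyond: more than half-width past the bound
    z_far <- if (row$orientation > 0) {
      row$x_min - 3 * half
    } else {
      row$x_max + 3 * half
    }
    probe[[cn]] <- row$mu + row$sigma * z_far
    sc2 <- score_regimes(probe, hm)
    expect_equal(
      as.character(sc2$bin[sc2$criterion == cn]), "well_below"
    )
    probe[[cn]] <- crit[[cn]][1]
  }
})

test_that("healthy model persistence round-trips", {
  hm <- fit_healthy_model(make_healthy_criteria())
  path <- withr::local_tempfile(fileext = ".json")
  write_healthy_model(hm, path)
  back <- read_healthy_model(path)
  expect_equal(tidy(back), tidy(hm), tolerance = 1e-12)
})
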