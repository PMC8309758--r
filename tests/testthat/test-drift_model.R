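test_that("an exact line is fitted with zero residual and no exclusions", {
  t <- seq(0, 6e5, by = 3600)
  obs <- data.frame(time_s = t, lag_samples = 0.001 * t + 5)
  fit <- fit_drift(obs)
  expect_equal(fit$beta1, 0.001, tolerance = 1e-12)
  expect_equal(fit$beta0, 5, tolerance = 1e-9)
  expect_equal(fit$rmse, 0)
  expect_equal(fit$n_used, length(t))
  expect_equal(nrow(fit$excluded), 0L)
  expect_false(fit$degenerate)
})

test_that("gross outliers are excluded and the clean line recovered", {
  t <- seq(0, 6e5, by = 3600)
  y <- 0.001 * t + 5
  bad <- c(10, 60, 120)
  y[bad] <- y[bad] + 500
  fit <- fit_drift(data.frame(time_s = t, lag_samples = y))
  # oracle: stats::lm on the clean subset
  clean <- lm(y[-bad] ~ t[-bad])
  expect_equal(fit$beta0, unname(coef(clean)[1]), tolerance = 1e-9)
  expect_equal(fit$beta1, unname(coef(clean)[2]), tolerance = 1e-12)
  expect_equal(sort(fit$excluded$block_index),
               sort(obs_block <- (bad - 1L)))
  expect_equal(fit$n_used, length(t) - 3L)
})

test_that("with no exclusions the fit equals textbook OLS", {
  set.seed(12)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    t <- sort(runif(n, 0, 6e5))
    y <- -0.002 * t + rnorm(n, sd = 0.5)
    ref <- lm(y ~ t)
    fit <- fit_drift(data.frame(time_s = t, lag_samples = y),
                     alignment_config(threshold_sequence = Inf))
    expect_equal(fit$beta0, unname(coef(ref)[1]), tolerance = 1e-9)
    expect_equal(fit$beta1, unname(coef(ref)[2]), tolerance = 1e-9)
    expect_equal(fit$rmse, summary(ref)$sigma, tolerance = 1e-9)
    expect_equal(fit$r2, summary(ref)$r.squared, tolerance = 1e-9)
  }
})

test_that("iteration thresholds follow the exponential recurrence", {
  expect_equal(accelalign:::drift_thresholds(alignment_config(), 1), 1)
  expect_equal(accelalign:::drift_thresholds(alignment_config(), 2), exp(1))
  expect_equal(accelalign:::drift_thresholds(alignment_config(), 3),
               exp(exp(1)))
  # printed sequence: 1, 2.7, 15.2 ...
  expect_equal(round(exp(1), 1), 2.7)
  expect_equal(round(exp(exp(1)), 1), 15.2)
  cfg <- alignment_config(threshold_sequence = c(2, 4))
  expect_equal(accelalign:::drift_thresholds(cfg, 2), 4)
  expect_equal(accelalign:::drift_thresholds(cfg, 3), Inf)
})

test_that("degenerate endgame keeps the previous fit and flags it", {
  # two tight points and one extreme: excluding the outlier leaves 2 points;
  # a further iteration that would go below 2 must stop and flag
  obs <- data.frame(time_s = c(0, 100, 200), lag_samples = c(0, 50, 0.2))
  fit <- fit_drift(obs)
  expect_true(is.finite(fit$beta1))
  # pathological two-point case: any exclusion would leave < 2
  obs2 <- data.frame(time_s = c(0, 100), lag_samples = c(0, 10))
  fit2 <- fit_drift(obs2)
  expect_equal(fit2$beta1, 0.1, tolerance = 1e-12)
  expect_equal(fit2$rmse, 0)
  expect_error(fit_drift(obs2[1, , drop = FALSE]), "at least 2")
  expect_error(fit_drift(data.frame(time_s = c(1, 1),
                                    lag_samples = c(0, 5))), "singular")
})

test_that("unit conversions follow the sampling-period arithmetic", {
  est <- to_alignment_estimate(list(beta0 = -12.8, beta1 = 0.001))
  expect_equal(est$accumulated_day7_s, 20.16, tolerance = 1e-12)
  expect_equal(est$initial_offset_s, -12.8 / 30, tolerance = 1e-12)
  expect_equal(round(est$initial_offset_s, 4), -0.4267)
  expect_equal(to_alignment_estimate(list(beta0 = 0, beta1 = 0))$accumulated_day7_s, 0)
  expect_equal(accumulated_day7_drift(0.001), 0.001 / 30 * 86400 * 7)
})

test_that("manual-marks arithmetic matches its closed form and negates", {
  est <- reference_from_manual_marks(10, 40, 3600, 603600)
  expect_equal(est$drift_samples_per_s, 5e-5, tolerance = 1e-15)
  expect_equal(est$fit$beta0, 9.82, tolerance = 1e-12)
  expect_equal(est$accumulated_day7_s, 1.008, tolerance = 1e-12)

  same <- reference_from_manual_marks(25, 25, 100, 200)
  expect_equal(same$drift_samples_per_s, 0)
  expect_equal(same$fit$beta0, 25)

  neg <- reference_from_manual_marks(-10, -40, 3600, 603600)
  expect_equal(neg$drift_samples_per_s, -est$drift_samples_per_s)
  expect_equal(neg$fit$beta0, -est$fit$beta0)
  expect_equal(neg$accumulated_day7_s, -est$accumulated_day7_s)

  expect_error(reference_from_manual_marks(0, 1, 50, 50), "exceed")
})

test_that("drift parameters are recovered under noise and gross outliers", {
  # 20% of observations replaced by uniform +-1000-sample garbage.  The
  # exponential threshold sequence removes gross outliers but lets moderate
  # ones (inside ~3 residual SDs of the second-pass fit) survive, so the
  # slope stays tight while the intercept degrades gracefully rather than
  # holding a hard bound; see the methods vignette on robustness limits.
  fs <- 30
  set.seed(99)
  b1_fail <- 0L
  b0_dev <- numeric(100)
  for (i in 1:100) {
    skew <- runif(1, -50, 50)
    offset <- runif(1, -10, 10)
    beta1 <- -skew * 1e-6 * fs
    beta0 <- -offset * fs
    t <- seq(0, 6.04e5, by = 3600)
    n <- length(t)
    y <- beta1 * t + beta0 + rnorm(n, sd = 1)
    n_out <- floor(0.2 * n)
    out_idx <- sample(n, n_out)
    y[out_idx] <- runif(n_out, -1000, 1000)
    fit <- fit_drift(data.frame(time_s = t, lag_samples = y))
    used <- setdiff(seq_len(n) - 1L, fit$excluded$block_index) + 1L
    se_beta1 <- fit$rmse / sqrt(sum((t[used] - mean(t[used]))^2))
    if (abs(fit$beta1 - beta1) >= 3 * max(se_beta1, 1e-8))
      b1_fail <- b1_fail + 1L
    b0_dev[i] <- abs(fit$beta0 - beta0)
  }
  expect_lte(b1_fail, 5L)                   # slope: nominal 3-sigma coverage
  expect_lt(median(b0_dev), 1.5)            # intercept: typically sub-sample
  expect_gte(mean(b0_dev < 2), 0.6)         # and usually inside 2 samples
  expect_lt(max(b0_dev), 30)                # never catastrophic
})
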