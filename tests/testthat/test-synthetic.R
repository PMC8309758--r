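test_that("clock and script constructors validate their inputs", {
  expect_error(clock_spec(2000), "sanity")
  expect_error(activity_script(data.frame(start_s = 1)), "invalid script")
  expect_error(activity_script(data.frame(
    start_s = c(0, 50), duration_s = c(100, 100), kind = "walk",
    amplitude_g = 0.5, step_hz = 2)), "overlapping")
  expect_error(activity_script(data.frame(
    start_s = 0, duration_s = 10, kind = "swim", amplitude_g = 0.5,
    step_hz = 2)), "unknown segment kind")
})

test_that("ground truth follows the relative clock model", {
  pair <- generate_pair(dense_script(1200), clock_spec(20, 2),
                        days = 1200 / 86400, seed = 1)
  expect_equal(pair$truth$fit$beta0, -2 * 30)
  expect_equal(pair$truth$fit$beta1, -20e-6 * 30)
  # 20 ppm accumulates ~12 s over 7 days; two devices at +-20 ppm ~24 s
  pair20 <- generate_pair(dense_script(1200), clock_spec(20, 0),
                          days = 1200 / 86400, seed = 1)
  expect_equal(abs(pair20$truth$accumulated_day7_s), 12.096)
  pair40 <- generate_pair(dense_script(1200), clock_spec(40, 0),
                          days = 1200 / 86400, seed = 1)
  expect_equal(abs(pair40$truth$accumulated_day7_s), 24.192, tolerance = 1e-6)
})

test_that("the lag sign convention is locked: a late secondary lags negative", {
  # offset_s = +1: the secondary samples 1 s later in true time, so shared
  # events sit ~30 samples EARLIER in its stream -> lag ~ -30
  cfg <- alignment_config(block_s = 300, max_lag_samples = 300)
  script <- dense_script(1800, bout_every_s = 300, bout_s = 120,
                         first_at_s = 30)
  pair <- generate_pair(script, clock_spec(0, 1), days = 1800 / 86400,
                        seed = 4)
  est <- estimate_alignment(pair$ref, pair$sec, cfg)
  expect_equal(stats::median(est$observations$lag_samples), -30, tolerance = 0.1)
})

test_that("identical clocks give a near-identity estimate", {
  cfg <- alignment_config(block_s = 600)
  script <- dense_script(2 * 3600, bout_every_s = 1200, bout_s = 240)
  pair <- generate_pair(script, clock_spec(0, 0), days = 2 / 24, seed = 9)
  est <- estimate_alignment(pair$ref, pair$sec, cfg)
  expect_lt(abs(est$fit$beta0), 2)
  expect_lt(abs(est$estimate$accumulated_day7_s), 0.5)
})

test_that("unshared bouts surface as drift-fit outliers", {
  cfg <- alignment_config(block_s = 600)
  duration <- 6 * 3600
  starts <- seq(60, duration - 300, by = 1200)
  kind <- rep("walk", length(starts))
  kind[seq_along(kind) %% 3 == 0] <- "unshared"
  script <- activity_script(data.frame(start_s = starts, duration_s = 240,
                                       kind = kind, amplitude_g = 0.6,
                                       step_hz = 2))
  hits <- 0L
  for (seed in 1:4) {
    pair <- generate_pair(script, clock_spec(200, 0.3), days = 0.25,
                          seed = seed)
    est <- estimate_alignment(pair$ref, pair$sec, cfg)
    unshared_blocks <- unique((starts[kind == "unshared"]) %/% 600)
    if (any(est$fit$excluded$block_index %in% unshared_blocks))
      hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})

test_that("the fixture suite is deterministic and truths round-trip", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_fixture_suite(d1, seed = 7, full_days = 0.05,
                            smoke_minutes = 4)
  m2 <- write_fixture_suite(d2, seed = 7, full_days = 0.05,
                            smoke_minutes = 4)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))

  # manifest ground truths round-trip through the manual-marks arithmetic
  for (p in m1$pairs) {
    b0 <- p$truth$beta0_samples
    b1 <- p$truth$beta1_samples_per_s
    marks <- reference_from_manual_marks(b0 + b1 * 1000, b0 + b1 * 5000,
                                         1000, 5000)
    expect_equal(marks$fit$beta0, b0, tolerance = 1e-9)
    expect_equal(marks$drift_samples_per_s, b1, tolerance = 1e-12)
    expect_equal(marks$accumulated_day7_s, p$truth$accumulated_day7_s,
                 tolerance = 1e-9)
  }
})

test_that("different seeds give different noise but the same truth", {
  s <- dense_script(900)
  a <- generate_pair(s, clock_spec(10, 0.5), days = 0.01, seed = 1)
  b <- generate_pair(s, clock_spec(10, 0.5), days = 0.01, seed = 2)
  expect_false(identical(a$ref$data, b$ref$data))
  expect_identical(a$truth$fit, b$truth$fit)
})
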