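test_that("day-7 drift bins follow the six reporting categories", {
  got <- drift_category(c(2, 12, 40, -7, 18, 25, 5, 30, 0))
  expect_equal(as.character(got),
               c("0-5", ">10-15", ">30", ">5-10", ">15-20", ">20-30",
                 "0-5", ">20-30", "0-5"))
})

test_that("run_estimate builds a report with category and flags", {
  cfg <- alignment_config(block_s = 600)
  script <- dense_script(4 * 3600, bout_every_s = 1200, bout_s = 240)
  # ~60 ppm -> ~36 s day-7 drift: beyond the 24 s manual-review rule
  pair <- generate_pair(script, clock_spec(60, 0.5), days = 4 / 24, seed = 2)
  rep <- run_estimate(pair$ref, pair$sec, cfg)
  expect_s3_class(rep, "run_report")
  expect_equal(rep$estimate$accumulated_day7_s, -36.288, tolerance = 0.05)
  expect_equal(rep$category, ">30")
  expect_true("manual_review" %in% rep$flags)

  # JSON report round-trips the key figures
  path <- withr::local_tempfile(fileext = ".json")
  write_report_json(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$beta1, rep$fit$beta1, tolerance = 1e-12)
  expect_equal(back$accumulated_day7_s, rep$estimate$accumulated_day7_s,
               tolerance = 1e-9)
  expect_equal(back$config$block_s, 600)

  # block diagnostics CSV has one row per block
  bpath <- withr::local_tempfile(fileext = ".csv")
  write_block_diagnostics(rep, bpath)
  diag <- data.table::fread(bpath)
  expect_equal(nrow(diag), nrow(attr(rep$observations, "gates")))
  expect_true(all(c("block_index", "active_ref", "active_sec", "used",
                    "lag_samples") %in% names(diag)))
})

test_that("run_align returns a corrected recording that closes the loop", {
  cfg <- alignment_config(block_s = 600)
  script <- dense_script(4 * 3600, bout_every_s = 1200, bout_s = 240)
  pair <- generate_pair(script, clock_spec(120, 1.0), days = 4 / 24, seed = 6)
  res <- run_align(pair$ref, pair$sec, cfg)
  expect_s3_class(res$aligned, "aligned_recording")
  re <- estimate_alignment(pair$ref, res$aligned$recording, cfg)
  expect_lt(abs(re$estimate$accumulated_day7_s), 0.5)
})

test_that("run_batch tabulates categories and tolerates failures", {
  cfg <- alignment_config(block_s = 600)
  script <- dense_script(2 * 3600, bout_every_s = 1200, bout_s = 240)
  p1 <- generate_pair(script, clock_spec(5, 0.2), days = 2 / 24, seed = 1)
  p2 <- generate_pair(script, clock_spec(100, -0.5), days = 2 / 24, seed = 2)
  pairs <- data.frame(id = c("a", "b", "bad"))
  pairs$ref <- I(list(p1$ref, p2$ref, flat_recording(30 * 1800)))
  pairs$sec <- I(list(p1$sec, p2$sec, flat_recording(30 * 1800)))
  res <- suppressWarnings(run_batch(pairs, cfg))
  expect_equal(nrow(res$summary), 3L)
  expect_equal(sum(res$histogram), 2)             # the failed pair drops out
  expect_match(res$summary$error[3], "insufficient")
  # 5 ppm -> ~3 s (0-5); 100 ppm -> ~60 s (>30)
  expect_equal(unname(res$histogram["0-5"]), 1L, ignore_attr = TRUE)
  expect_equal(unname(res$histogram[">30"]), 1L, ignore_attr = TRUE)
  expect_error(run_batch(data.frame()), "empty manifest")
})

test_that("the CLI estimates a simulated pair and signals insufficiency", {
  cli <- system.file("cli", "accelalign.R", package = "accelalign")
  expect_true(nzchar(cli))
  rscript <- file.path(R.home("bin"), "Rscript")
  tmp <- withr::local_tempdir()

  # config for the short smoke fixture
  cfgfile <- file.path(tmp, "cfg.yaml")
  writeLines(c("block_s: 60", "max_lag_samples: 300"), cfgfile)
  write_fixture_suite(tmp, seed = 3, full_days = 0.05, smoke_minutes = 4)
  rep_json <- file.path(tmp, "fit.json")
  out <- system2(rscript, c(cli, "estimate",
                            "--ref", file.path(tmp, "smoke_ref.csv"),
                            "--sec", file.path(tmp, "smoke_sec.csv"),
                            "--config", cfgfile, "--report", rep_json),
                 stdout = TRUE, stderr = TRUE)
  expect_null(attr(out, "status"))  # exit 0
  expect_true(file.exists(rep_json))
  fit <- jsonlite::read_json(rep_json)
  # smoke truth: offset 0.5 s -> beta0 ~ -15 samples
  expect_equal(fit$beta0, -15, tolerance = 0.15)

  # a sedentary pair exits with the data-insufficiency code 2
  sed <- file.path(tmp, "sed.csv")
  write_acc_csv(flat_recording(30 * 300), sed)
  res <- suppressWarnings(
    system2(rscript, c(cli, "estimate", "--ref", sed, "--sec", sed,
                       "--config", cfgfile),
            stdout = TRUE, stderr = TRUE))
  expect_equal(attr(res, "status"), 2L)
})
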