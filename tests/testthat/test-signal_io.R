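test_that("CSV header dialect round-trips a recording", {
  rec <- acc_recording(matrix(c(0.1, -0.2, 0.98, 0, 0, 1, 0.3, 0.2, 1.1),
                              3, 3, byrow = TRUE),
                       fs = 30, start_time = 1.6e9, device_id = "d1")
  path <- withr::local_tempfile(fileext = ".csv")
  write_acc_csv(rec, path)
  back <- read_acc_csv(path)
  expect_equal(back$data, rec$data, tolerance = 1e-12)
  expect_equal(back$fs, 30)
  expect_equal(back$start_time, 1.6e9)
})

test_that("CSV timestamp dialect parses, infers the rate, and validates", {
  path <- withr::local_tempfile(fileext = ".csv")
  ts <- 100 + (0:29) / 30
  writeLines(c("timestamp,x,y,z",
               sprintf("%.9f,0,0,1", ts)), path)
  rec <- read_acc_csv(path)
  expect_equal(rec$fs, 30, tolerance = 1e-6)
  expect_equal(n_samples(rec), 30L)
  expect_equal(rec$start_time, 100)

  # missing columns -> format error
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,x,y", "0,0,0"), bad)
  expect_error(read_acc_csv(bad), "format error")

  # a gap larger than 2/fs -> data error naming the first gap
  gap <- withr::local_tempfile(fileext = ".csv")
  ts2 <- c(ts[1:10], ts[11:30] + 0.5)
  writeLines(c("timestamp,x,y,z", sprintf("%.9f,0,0,1", ts2)), gap)
  expect_error(read_acc_csv(gap), "data error.*gap.*row 11")

  # non-monotone timestamps -> data error
  mono <- withr::local_tempfile(fileext = ".csv")
  ts3 <- ts
  ts3[5] <- ts3[7]
  writeLines(c("timestamp,x,y,z", sprintf("%.9f,0,0,1", ts3)), mono)
  expect_error(read_acc_csv(mono), "non-monotone")
})

test_that("stereo WAV round-trips in float32 and int16", {
  set.seed(42)
  ch1 <- rnorm(3000, 1, 0.2)
  ch2 <- rnorm(3000, 1, 0.2)
  fwav <- withr::local_tempfile(fileext = ".wav")
  write_wav_vm(ch1, ch2, fs = 30, fwav, format = "float32")
  got <- read_wav_vm(fwav)
  expect_equal(got$fs, 30)
  expect_equal(got$channels[[1]], ch1, tolerance = 1e-6)
  expect_equal(got$channels[[2]], ch2, tolerance = 1e-6)

  iwav <- withr::local_tempfile(fileext = ".wav")
  write_wav_vm(ch1, ch2, fs = 30, iwav, format = "int16", scale = 4096)
  got2 <- read_wav_vm(iwav)
  expect_equal(got2$scale, 4096)
  expect_equal(got2$channels[[1]], ch1, tolerance = 1 / 4096)
})

test_that("mono WAV is rejected with a format error", {
  # hand-built mono PCM file
  path <- withr::local_tempfile(fileext = ".wav")
  con <- file(path, "wb")
  samp <- as.integer(round(sin(2 * pi * 2 * (0:299) / 30) * 1000))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(samp)), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")   # PCM
  writeBin(1L, con, 2, endian = "little")   # 1 channel
  writeBin(30L, con, 4, endian = "little")
  writeBin(60L, con, 4, endian = "little")
  writeBin(2L, con, 2, endian = "little")
  writeBin(16L, con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(samp)), con, 4, endian = "little")
  writeBin(samp, con, 2, endian = "little")
  close(con)
  expect_error(read_wav_vm(path), "2-channel")
})

test_that("resampling to the working rate is exact on affine signals", {
  # constants are preserved
  rec <- flat_recording(1000, fs = 100)
  out <- resample_recording(rec, 30)
  expect_equal(out$fs, 30)
  expect_equal(n_samples(out), floor(999 / 100 * 30) + 1L)
  expect_true(all(abs(out$data[, 3] - 1) < 1e-12))

  # a ramp is reproduced exactly by linear interpolation
  n <- 500
  t50 <- (0:(n - 1)) / 50
  ramp <- acc_recording(cbind(t50, 0, 1), fs = 50, range_g = 100)
  out2 <- resample_recording(ramp, 30)
  t30 <- (0:(n_samples(out2) - 1)) / 30
  expect_lt(max(abs(out2$data[, 1] - t30)), 1e-9)

  # idempotence at the target rate: identical object back
  expect_identical(resample_recording(out2, 30), out2)
})

test_that("resampled sinusoid matches the closed form", {
  n <- 1000
  t100 <- (0:(n - 1)) / 100
  rec <- acc_recording(cbind(sin(2 * pi * t100), 0, 1), fs = 100)
  out <- resample_recording(rec, 30)
  t30 <- (0:(n_samples(out) - 1)) / 30
  expect_lt(max(abs(out$data[, 1] - sin(2 * pi * t30))), 1e-3)
})

test_that("recording construction validates range and finiteness", {
  expect_error(acc_recording(matrix(9, 2, 3), fs = 30), "measurement range")
  expect_error(acc_recording(matrix(NA_real_, 2, 3), fs = 30), "finite")
  expect_error(acc_recording(matrix(0, 2, 2), fs = 30), "3 columns")
  expect_error(acc_recording(matrix(0, 2, 3), fs = -1), "positive")
})
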