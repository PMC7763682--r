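# Record and annotation I/O: round trips, rescaling, error kinds.

test_that("CSV record round-trips and rejects malformed input", {
  x <- cbind(sin(2 * pi * 2 * (0:999) / 250), cos(2 * pi * 2 * (0:999) / 250))
  rec <- ecg_record(x, fs = 250, channel_names = c("I", "II"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ecg(rec, path, "csv")
  back <- read_ecg(path, "csv")
  expect_equal(back$fs, 250)
  expect_equal(back$n_samples, 1000L)
  expect_equal(back$samples, rec$samples, ignore_attr = TRUE,
               tolerance = 1e-6)

  flat <- file.path(withr::local_tempdir(), "flat.csv")
  writeLines(c("fs=250", rep("0", 250)), flat)
  cflat <- read_ecg(flat, "csv")
  expect_equal(cflat$n_samples, 250L)
  expect_true(all(cflat$samples == 0))

  expect_error(read_ecg(file.path(tempdir(), "nope.csv"), "csv"),
               class = "tendos_missing_file")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("hello", "1"), bad)
  expect_error(read_ecg(bad, "csv"), class = "tendos_malformed_header")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("fs=250", empty)
  expect_error(read_ecg(empty, "csv"), class = "tendos_empty_signal")
})

test_that("WFDB record round-trips with channels preserved and bytes as documented", {
  x <- cbind(0.5 * sin(2 * pi * (0:499) / 250), rep(c(-1, 1), 250))
  rec <- ecg_record(x, fs = 250, channel_names = c("MLII", "V5"),
                    record_id = "tt01")
  dir <- withr::local_tempdir()
  base <- file.path(dir, "tt01")
  write_ecg(rec, base, "wfdb")
  back <- read_ecg(base, "wfdb")
  expect_equal(length(back$channel_names), 2L)
  expect_equal(back$channel_names, c("MLII", "V5"))
  expect_equal(nrow(back$samples), 500L)
  # storage precision: gain 1000 adu/mV => 0.0005 mV quantisation
  expect_lt(max(abs(back$samples - rec$samples)), 5e-4 + 1e-12)

  # byte-level check against the declared format-16 layout: interleaved
  # little-endian int16, adc = round(mv * gain)
  raw <- readBin(paste0(base, ".dat"), "integer", n = 1000, size = 2,
                 signed = TRUE, endian = "little")
  expect_equal(raw[1:4], as.integer(round(c(x[1, ], x[2, ]) * 1000)))
  expect_error(read_ecg(file.path(dir, "missing"), "wfdb"),
               class = "tendos_missing_file")
})

test_that("non-finite samples: short runs interpolated, long runs rejected", {
  x <- as.numeric(1:100)
  x[40:43] <- NA
  rec <- ecg_record(x, fs = 100)
  expect_equal(rec$samples[40:43, 1], as.numeric(40:43))
  x[40:46] <- NA
  expect_error(ecg_record(x, fs = 100), class = "tendos_nonfinite_run")
})

test_that("annotation files round-trip in both formats (0-based on disk)", {
  ann <- ann_series(c(11L, 21L, 31L), kind = "rpeak", fs = 250,
                    source = "manual")
  csvp <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, csvp, "csv")
  expect_equal(utils::read.csv(csvp, header = FALSE, skip = 1)[[1]],
               c(10L, 20L, 30L))  # 0-based on disk
  back <- read_annotations(csvp, "csv")
  expect_equal(back$indices, ann$indices)
  expect_equal(back$kind, "rpeak")

  # empty series -> empty but valid file
  ann0 <- ann_series(integer(0), kind = "tend", fs = 250)
  p0 <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann0, p0, "csv")
  expect_length(read_annotations(p0)$indices, 0L)

  # binary MIT-format round trip, including a long gap through SKIP words
  wp <- withr::local_tempfile(fileext = ".atr")
  ann_long <- ann_series(c(100L, 2000L, 90000L), kind = "rpeak", fs = 250)
  write_annotations(ann_long, wp, "wfdb_ann")
  expect_equal(read_annotations(wp, "wfdb_ann")$indices, ann_long$indices)

  expect_error(ann_series(c(10L, 5L), "rpeak", 250),
               class = "tendos_non_monotone")
})

test_that("resampling preserves duration, content and survives a round trip", {
  rec250 <- ecg_record(rep(0, 250), fs = 250)
  expect_identical(resample_record(rec250, 250), rec250)

  t200 <- (0:1999) / 200
  rec <- ecg_record(sin(2 * pi * 1 * t200), fs = 200)
  up <- resample_record(rec, 250)
  expect_equal(up$fs, 250)
  expect_true(abs(up$n_samples - 2500) <= 1)
  ref <- sin(2 * pi * 1 * (seq_len(up$n_samples) - 1) / 250)
  expect_gt(stats::cor(up$samples[, 1], ref), 0.999)

  # band-limited a -> b -> a round trip within 1% RMS (interior, away from
  # the filter's edge ramps)
  x <- sin(2 * pi * 7 * t200) + 0.5 * sin(2 * pi * 13 * t200)
  rt <- resample_record(resample_record(ecg_record(x, 200), 250), 200)
  core <- 101:1900
  expect_lt(sqrt(mean((rt$samples[core, 1] - x[core])^2)) / sqrt(mean(x[core]^2)),
            0.01)
  expect_error(resample_record(rec, -5), class = "tendos_bad_fs")
})
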