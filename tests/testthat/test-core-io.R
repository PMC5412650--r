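test_that("type constructors enforce their invariants", {
  expect_error(timeseries(numeric(0), 100), class = "hp_invariant_error")
  expect_error(timeseries(c(1, NaN), 100), class = "hp_invariant_error")
  expect_error(timeseries(1:10, -5), class = "hp_invariant_error")
  expect_error(event_series(c(1, 1)), class = "hp_invariant_error")
  expect_error(event_series(c(2, 1)), class = "hp_invariant_error")
  # channels must share a span (within one sample of the slowest channel)
  expect_error(
    recording(list(a = timeseries(rnorm(100), 100),
                   b = timeseries(rnorm(50), 100))),
    class = "hp_invariant_error")
  # but different rates over the same span are fine
  rec <- recording(list(a = timeseries(rnorm(1000), 1000),
                        b = timeseries(rnorm(250), 250)))
  expect_equal(unname(vapply(rec$channels, ts_duration, numeric(1))), c(1, 1))
})

test_that("recordings round-trip through the delimited-text format", {
  withr::local_seed(42)
  dir <- withr::local_tempdir()
  rec <- recording(
    channels = list(
      chest = timeseries(rnorm(2000), 1000, label = "chest", units = "a.u."),
      neck = timeseries(rnorm(2000) * 1e-7, 1000, label = "neck", units = "a.u."),
      belt = timeseries(sin(seq_len(500) / 40), 250, label = "belt", units = "V")
    ),
    markers = list(beats = event_series(c(0.5, 1.1, 1.9), "beats"),
                   hold_onset = event_series(1.25, "hold_onset")),
    metadata = list(subject = "s01", session = "sim")
  )
  path <- file.path(dir, "rec.csv")
  write_recording(rec, path)
  back <- read_recording(path)

  expect_equal(names(back$channels), names(rec$channels))
  for (nm in names(rec$channels)) {
    expect_equal(back$channels[[nm]]$samples, rec$channels[[nm]]$samples,
                 tolerance = 1e-9)
    expect_identical(back$channels[[nm]]$fs, rec$channels[[nm]]$fs)
    expect_identical(back$channels[[nm]]$units, rec$channels[[nm]]$units)
  }
  expect_equal(back$markers$beats$times, c(0.5, 1.1, 1.9))
  expect_equal(back$markers$hold_onset$times, 1.25)
  expect_equal(back$metadata$subject, "s01")

  # mixed-rate channels keep their declared rates and lengths
  expect_equal(length(back$channels$belt$samples), 500L)
  expect_equal(back$channels$belt$fs, 250)
})

test_that("declared rate times duration fixes the sample count on re-read", {
  dir <- withr::local_tempdir()
  rec <- recording(setNames(
    lapply(1:5, function(i) timeseries(rnorm(10000), 1000, label = paste0("ch", i))),
    paste0("ch", 1:5)))
  path <- file.path(dir, "five.csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(unname(vapply(back$channels, function(ch) length(ch$samples), integer(1))),
               rep(10000L, 5))
})

test_that("an empty marker set writes no marker file and re-reads as empty", {
  dir <- withr::local_tempdir()
  rec <- recording(list(a = timeseries(1:100, 100, label = "a")))
  path <- file.path(dir, "plain.csv")
  write_recording(rec, path)
  expect_false(file.exists(file.path(dir, "plain_markers.tsv")))
  expect_length(read_recording(path)$markers, 0)
})

test_that("the reader rejects malformed files instead of repairing them", {
  dir <- withr::local_tempdir()
  rec <- recording(list(a = timeseries(rnorm(100), 100, label = "a"),
                        b = timeseries(rnorm(100), 100, label = "b")))
  path <- file.path(dir, "rec.csv")
  write_recording(rec, path)

  # duplicate channel label in the header
  lines <- readLines(path)
  dup <- sub("^a,b", "a,a", lines)
  writeLines(dup, path)
  expect_error(read_recording(path), class = "hp_format_error")
  writeLines(lines, path)

  # non-numeric sample reports the offending line
  lines2 <- lines
  lines2[13] <- "oops,0.1"
  writeLines(lines2, path)
  err <- expect_error(read_recording(path), class = "hp_parse_error")
  expect_match(conditionMessage(err), "line 13")
  writeLines(lines, path)

  # missing sidecar is fatal, not silently defaulted
  unlink(sidecar <- sub("\\.csv$", ".json", path))
  expect_error(read_recording(path), class = "hp_format_error")
})

test_that("marker files round-trip through read_markers/write_markers", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "mk.tsv")
  write_markers(list(a = event_series(c(1, 2, 3.5), "a"),
                     b = event_series(10, "b")), path)
  back <- read_markers(path)
  expect_equal(back$a$times, c(1, 2, 3.5))
  expect_equal(back$b$times, 10)
})
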