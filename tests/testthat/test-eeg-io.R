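test_that("EDF round-trips within 16-bit quantization", {
  set.seed(30)
  rec <- continuous_recording(matrix(rnorm(3 * 730, sd = 25), 3), 100,
                              c("C3", "Cz", "C4"))
  f <- withr::local_tempfile(fileext = ".edf")
  write_continuous(rec, f, "edf")
  r2 <- read_continuous(f, "edf")
  expect_identical(r2$channel_names, rec$channel_names)
  expect_equal(r2$fs, rec$fs)
  qstep <- max(abs(rec$data)) / 32767
  expect_lt(max(abs(r2$data - rec$data)), qstep)
})

test_that("CSV continuous I/O uses the JSON sidecar for metadata", {
  rec <- continuous_recording(matrix(0, 3, 40), 128, c("C3", "C4", "Cz"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_continuous(rec, f, "csv")
  r2 <- read_continuous(f, "csv")
  expect_true(all(r2$data == 0))
  expect_equal(r2$fs, 128)
  expect_identical(r2$channel_names, rec$channel_names)
  file.remove(paste0(f, ".json"))
  expect_error(read_continuous(f, "csv"), "sidecar")
})

test_that("malformed EDF headers and truncated payloads are rejected", {
  set.seed(31)
  rec <- continuous_recording(matrix(rnorm(2 * 100), 2), 100, c("C3", "C4"))
  f <- withr::local_tempfile(fileext = ".edf")
  write_continuous(rec, f, "edf")
  # corrupt the signal-count header field
  raw <- readBin(f, "raw", file.size(f))
  raw[253:256] <- charToRaw("99  ")
  f_bad <- withr::local_tempfile(fileext = ".edf")
  writeBin(raw, f_bad)
  expect_error(read_continuous(f_bad, "edf"), "malformed EDF")
  # truncate the data records
  f_tr <- withr::local_tempfile(fileext = ".edf")
  writeBin(raw[1:(length(raw) - 10)], f_tr)
  expect_error(read_continuous(f_tr, "edf"), "malformed EDF")
  expect_error(read_continuous("does-not-exist.edf", "edf"), "not found")
})

test_that("epoch extraction cuts half-open windows and drops out-of-bounds", {
  fs <- 100
  n <- 280 * 600 + 400
  rec <- continuous_recording(matrix(rnorm(2 * n), 2), fs, c("C3", "C4"))
  onsets <- seq(300, by = 600, length.out = 280)
  ev <- event_table(onsets, rep(c("left", "right"), 140))
  es <- epoch_extract(rec, ev, c(-2, 3.5))
  expect_equal(n_trials(es), 280)
  expect_equal(n_samples(es), 550)            # (3.5 - (-2)) * 100
  expect_equal(es$cue_index, 200L)
  expect_equal(as.vector(table(es$labels)), c(140L, 140L))
  # content check: first epoch equals the raw slice [onset-200, onset+350)
  expect_identical(es$data[1, , ], rec$data[, 101:650])
  # an event too close to the start is dropped with a message
  ev2 <- event_table(c(10, onsets), c("left", rep(c("left", "right"), 140)))
  expect_message(es2 <- epoch_extract(rec, ev2, c(-2, 3.5)), "dropped")
  expect_equal(n_trials(es2), 280)
  # all-out-of-bounds is an error, as is a degenerate window
  ev3 <- event_table(10, "left")
  expect_error(epoch_extract(rec, ev3, c(-2, 3.5)), "no valid epochs")
  expect_error(epoch_extract(rec, ev, c(0, 0)), "window")
  expect_error(epoch_extract(rec, ev, c(1, 2)), "contain the cue")
})

test_that("event tables validate and round-trip through CSV", {
  ev <- event_table(c(5, 50, 500), c("left", "right", "left"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, f)
  ev2 <- read_events(f)
  expect_equal(ev2$onset_sample, ev$onset_sample)
  expect_equal(as.character(ev2$label), as.character(ev$label))
  expect_error(event_table(c(5, 5), c("left", "right")), "increasing")
  expect_error(event_table(c(5, 50), c("left", "up")), "left")
})

test_that("the epochs container round-trips bit-identically", {
  es <- generate_session(generator_config(n_trials_per_class = 4L,
                                          seed = 33L))
  d <- withr::local_tempdir()
  write_epochs(es, d)
  es2 <- read_epochs(d)
  expect_identical(es2$data, es$data)
  expect_identical(as.character(es2$labels), as.character(es$labels))
  expect_identical(es2$channel_names, es$channel_names)
  expect_equal(es2$cue_index, es$cue_index)
  expect_equal(es2$provenance$seed, es$provenance$seed)
})

test_that("the epochs container detects corruption and inconsistency", {
  es <- generate_session(generator_config(n_trials_per_class = 3L,
                                          seed = 34L))
  d <- withr::local_tempdir()
  write_epochs(es, d)
  # flip bytes in the payload -> checksum mismatch
  bin <- file.path(d, "data.bin")
  raw <- readBin(bin, "raw", file.size(bin))
  raw[1001:1040] <- as.raw(255)
  writeBin(raw, bin)
  expect_error(read_epochs(d), "checksum|corrupt")
  # sidecar label count inconsistent with trial count
  d2 <- withr::local_tempdir()
  write_epochs(es, d2)
  meta <- jsonlite::read_json(file.path(d2, "epochs.json"),
                              simplifyVector = TRUE)
  meta$labels <- meta$labels[-1]
  jsonlite::write_json(meta, file.path(d2, "epochs.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(read_epochs(d2), "labels")
  # writing an empty set is refused
  empty <- subset_epochs(es, integer(0))
  expect_error(write_epochs(empty, withr::local_tempdir()), "empty")
})
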