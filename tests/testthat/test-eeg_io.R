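test_that("channel labels canonicalize case-insensitively with aliases", {
  expect_equal(canonicalize_label("EEG Fp1-Ref"), "fp1")
  expect_equal(canonicalize_label("EEG FP2-REF"), "fp2")
  expect_equal(canonicalize_label("fz-LE"), "fz")
  # modern 10-20 names map onto the legacy canonical set
  expect_equal(canonicalize_label(c("T7", "T8", "P7", "P8")),
               c("t3", "t4", "t5", "t6"))
  # non-EEG channels return NA
  expect_true(is.na(canonicalize_label("ECG")))
  expect_true(is.na(canonicalize_label("A1")))
  expect_equal(canonicalize_label(c("Cz", "EEG O1-Ref")), c("cz", "o1"))
})

test_that("select_channels extracts the 19 canonical channels in order", {
  labels <- c(paste0("EEG ", toupper(canonical_19), "-Ref"), "ECG", "A1")
  rec <- tiny_recording(2, 100, seed = 2, labels = labels)
  sel <- select_channels(rec)
  expect_equal(nrow(sel$data), 19L)
  expect_equal(sel$channel_labels, canonical_19)
  # rows carried over correctly (fp1 is the 1st input row, pz the 19th)
  expect_equal(unname(sel$data["pz", ]), unname(rec$data[19, ]))

  # idempotence
  expect_equal(select_channels(sel)$data, sel$data)

  # missing channel is an error naming the channel
  rec_miss <- tiny_recording(2, 100, seed = 2, labels = labels[-19])
  expect_error(select_channels(rec_miss), "pz")

  # duplicate resolution is an ambiguity error, not first-wins
  rec_dup <- tiny_recording(2, 100, seed = 2,
                            labels = c(canonical_19, "T7"))
  expect_error(select_channels(rec_dup), "ambiguous")
})

test_that("resampling preserves length arithmetic and in-band content", {
  n <- 5000
  x <- sin(2 * pi * 3 * (0:(n - 1)) / 500)
  rec <- recording(rbind(x, x), 500, c("a", "b"),
                   annotations = event_list(2, 6))
  out <- resample_recording(rec, 100)
  expect_equal(ncol(out$data), 1000L)   # round(5000 * 100/500)
  expect_equal(out$fs, 100)
  # annotations are in seconds: unchanged
  expect_equal(out$annotations, rec$annotations)
  # 3 Hz sinusoid amplitude preserved within 1% against the analytic form
  ref <- sin(2 * pi * 3 * (0:999) / 100)
  expect_lt(max(abs(out$data[1, ] - ref)), 0.01)

  # identity resample returns data unchanged
  expect_equal(resample_recording(rec, 500)$data, rec$data)
})

test_that("resampling preserves in-band energy within 1% for sinusoids", {
  for (f0 in c(2, 11, 27)) {
    x <- sin(2 * pi * f0 * (0:9999) / 500)
    rec <- recording(matrix(x, 1), 500, "c1")
    y <- resample_recording(rec, 100)$data[1, ]
    e_ratio <- mean(y^2) / mean(x^2)
    expect_lt(abs(e_ratio - 1), 0.01)
  }
})

test_that("EDF round trip reproduces data within 16-bit quantization", {
  rec <- tiny_recording(60, 100, seed = 3,
                        events = event_list(c(10, 30), c(20, 35)))
  f <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, f)
  back <- read_recording(f)
  expect_equal(dim(back$data), c(19L, 6000L))
  expect_equal(back$fs, 100)
  # quantization step is 2 * physmax / 65535
  step <- 2 * max(abs(rec$data)) * 1.0001 / 65535
  expect_lt(max(abs(back$data - rec$data)), step)
  # annotations come back through the sidecar CSV
  expect_equal(back$annotations$start_s, c(10, 30))
})

test_that("EDF read preserves labels verbatim and parses EDF+ annotations", {
  labels <- c(paste0("EEG ", toupper(canonical_19[1:18]), "-Ref"),
              "EEG FP2-REF")
  rec <- tiny_recording(5, 100, seed = 4, labels = labels,
                        events = event_list(c(1, 3), c(2, 4.5)))
  f <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, f, edfplus_annotations = TRUE, sidecar = FALSE)
  back <- read_recording(f)
  expect_equal(back$channel_labels, labels)   # no silent renaming
  expect_equal(back$annotations$start_s, c(1, 3))
  expect_equal(back$annotations$end_s, c(2, 4.5))
})

test_that("internal dialect round-trips exactly", {
  rec <- tiny_recording(3, 250, seed = 5, events = event_list(1, 2))
  f <- withr::local_tempfile(fileext = ".rds")
  write_recording(rec, f, dialect = "internal")
  expect_equal(read_recording(f, dialect = "internal"), rec)
})

test_that("unreadable or missing files raise format errors", {
  f <- withr::local_tempfile(fileext = ".edf")
  writeBin(as.raw(1:64), f)
  expect_error(read_recording(f))
  expect_error(read_recording(file.path(tempdir(), "absent.edf")),
               "not found")
})

test_that("recording constructor enforces its invariants", {
  expect_error(recording(matrix(1, 2, 10), 100, "one"), "channel_labels")
  expect_error(recording(matrix(NA_real_, 1, 5), 100, "a"), "finite")
  expect_error(recording(matrix(1, 1, 5), -1, "a"), "positive")
  expect_error(recording(matrix(1, 1, 500), 100,
                         annotations = event_list(2, 10)),
               "within")
})

test_that("recordings tidy into long format and plot", {
  rec <- tiny_recording(2, 100, seed = 13, events = event_list(0.5, 1.5))
  td <- generics::tidy(rec, channels = c("fp1", "cz"))
  expect_equal(nrow(td), 2L * 200L)
  expect_equal(levels(td$channel), c("fp1", "cz"))
  expect_equal(td$uv[1:200], unname(rec$data["fp1", ]))
  p <- ggplot2::autoplot(rec, channels = c("fp1", "cz"), t_lim = c(0, 1))
  expect_s3_class(p, "ggplot")
})
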