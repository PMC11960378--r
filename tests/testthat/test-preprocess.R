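# Band-pass filter -------------------------------------------------------

test_that("band-pass design puts half-power edges at the cutoffs", {
  sos <- butter_sos(filter_spec(), 500)
  expect_equal(nrow(sos), 6L)            # order 12 = 6 pole pairs
  H <- abs(sos_freqz(sos, c(0.16, 35), 500))
  expect_equal(H, rep(1 / sqrt(2), 2), tolerance = 1e-6)
  # all section poles strictly inside the unit circle
  expect_true(all(sos[, 6] < 1))
})

test_that("DC is rejected, 3 Hz passes, 50 Hz is attenuated", {
  spec <- filter_spec()
  # constant input -> essentially zero after the transient
  rec <- recording(matrix(7, 1, 6000), 100, "c1")
  y <- bandpass_filter(rec, spec)$data[1, ]
  expect_lt(max(abs(y[2500:3500])), 1e-3 * 7)

  # 3 Hz unit sinusoid at fs 100: designed transfer magnitude in [0.95, 1]
  h3 <- abs(sos_freqz(butter_sos(spec, 100), 3, 100))
  expect_gte(h3, 0.95)
  expect_lte(h3, 1.0)

  # 50 Hz at fs 500: zero-phase amplitude < 0.05
  x <- sin(2 * pi * 50 * (0:9999) / 500)
  y50 <- bandpass_filter(recording(matrix(x, 1), 500, "c1"), spec)$data[1, ]
  expect_lt(max(abs(y50[4000:6000])), 0.05)
})

test_that("filter design rejects infeasible sampling rates", {
  expect_error(butter_sos(filter_spec(), 60), "Nyquist")
  expect_error(filter_spec(low_cut_hz = 40, high_cut_hz = 35))
  expect_error(filter_spec(order = 7))
})

test_that("filtering then downsampling commutes with the reverse order
           for in-band sinusoids", {
  spec <- filter_spec()
  for (f0 in c(3, 9)) {
    x <- sin(2 * pi * f0 * (0:14999) / 500)
    rec <- recording(matrix(x, 1), 500, "c1")
    a <- resample_recording(bandpass_filter(rec, spec), 100)$data[1, ]
    b <- bandpass_filter(resample_recording(rec, 100), spec)$data[1, ]
    mid <- 1000:2000
    expect_lt(max(abs(a[mid] - b[mid])) / max(abs(b[mid])), 0.02)
  }
})

# STFT --------------------------------------------------------------------

test_that("stft matches the brute-force direct-sum oracle", {
  set.seed(11)
  sp <- stft_spec(window_len = 128, hop = 64)
  h <- swdnet:::taper("hann", 128)
  for (k in 1:5) {
    x <- rnorm(sample(300:800, 1))
    S <- stft_frames(x, sp, 100)
    O <- stft_oracle(x, 128, 64, h)
    expect_lt(relerr(S, O), 1e-9)
  }
})

test_that("stft edge cases: zeros, exact-bin sinusoid, frame count", {
  sp <- stft_spec(window_len = 64, hop = 32, window_fn = "rect")
  expect_true(all(stft_frames(numeric(200), sp, 100) == 0))

  # unit sinusoid exactly at bin 5 with rectangular taper: energy confined
  wl <- 64L
  x <- cos(2 * pi * 5 * (0:255) / wl)
  S <- stft_frames(x, sp, 100)
  mags <- Mod(S[1, ])
  # a real cosine has conjugate peaks at bins 5 and 59; everything else
  # is orthogonal-bin leakage at numerical zero
  expect_equal(which.max(mags[1:(wl / 2)]), 6L)   # bin 5, 0-based
  expect_lt(max(mags[-c(6L, wl - 4L)]) / max(mags), 1e-9)

  expect_equal(nrow(S), (256 - 64) %/% 32 + 1)
  expect_error(stft_frames(numeric(10), sp, 100), "shorter")
})

# Combined features -------------------------------------------------------

test_that("combined features are 128 log-spectrogram + 128 raw values", {
  rec <- tiny_recording(10, 100, seed = 6)
  feats <- combined_features(rec, stft_spec())
  expect_equal(dim(feats), c((1000 - 256) %/% 128 + 1, 256L, 19L))

  # zero signal -> all-zero features (log1p(0) = 0, raw 0)
  zrec <- recording(matrix(0, 19, 1000), 100, canonical_19)
  expect_true(all(combined_features(zrec, stft_spec()) == 0))

  # spectral half of a 3 Hz wave peaks near bin round(3*256/100) = 8
  x <- sin(2 * pi * 3 * (0:999) / 100) * 50
  srec <- recording(matrix(rep(x, 19), 19, byrow = TRUE), 100, canonical_19)
  sf <- combined_features(srec, stft_spec())
  peak_bin <- which.max(sf[2, 1:128, 1]) - 1L   # 0-based bin
  expect_lte(abs(peak_bin - 8L), 1L)

  # raw half equals the decimated window
  ft <- attr(feats, "frame_times")
  expect_equal(unname(feats[3, 129:256, 5]),
               unname(rec$data[5, (2 * 128) + seq(1, 256, by = 2)]))
  # frame times tile the record at the constant hop
  expect_equal(diff(ft[, 1]), rep(1.28, nrow(ft) - 1))
})

test_that("non-canonical feature assembly is a configuration error", {
  rec <- tiny_recording(5, 100, seed = 7)
  expect_error(combined_features(rec, stft_spec(window_len = 128)),
               "256")
})

# Normalization -----------------------------------------------------------

test_that("normalization z-scores raw halves and is scale invariant", {
  rec <- tiny_recording(30, 100, seed = 8)
  ex <- make_examples(rec, event_list(), stft_spec())
  nx <- normalize_examples(ex, stft_spec())
  live <- nx[[1]]$mask > 0
  for (ch in c(1, 10)) {
    raw <- unlist(lapply(nx, function(e) e$x[e$mask > 0, 129:256, ch]))
    expect_lt(abs(mean(raw)), 1e-6)
    expect_equal(sd(raw), 1, tolerance = 1e-6)
  }
  # scaling microvolts by 10 leaves the z-scored raw half unchanged
  # (the spectrogram half is sd-scaled but not centered, and log(1+|X|)
  # is not scale-equivariant, so exact invariance applies to the
  # z-scored features)
  rec10 <- recording(rec$data * 10, rec$fs, rec$channel_labels,
                     record_id = rec$record_id)
  nx10 <- normalize_examples(make_examples(rec10, event_list(),
                                           stft_spec()), stft_spec())
  expect_lt(max(abs(nx10[[1]]$x[, 129:256, ] - nx[[1]]$x[, 129:256, ])),
            1e-6)
})

test_that("constant channels normalize to zeros", {
  data <- matrix(rnorm(19 * 1000, sd = 10), 19, 1000)
  data[4, ] <- 5                      # constant channel
  rec <- recording(data, 100, canonical_19)
  ex <- make_examples(rec, event_list(), stft_spec())
  expect_message(nx <- normalize_examples(ex, stft_spec()), "degenerate")
  expect_true(all(nx[[1]]$x[nx[[1]]$mask > 0, 129:256, 4] == 0))
})

# Example framing and labeling -------------------------------------------

test_that("framing arithmetic: 60 s at 100 Hz gives 45 frames, 1 example", {
  rec <- tiny_recording(60, 100, seed = 9)
  ex <- make_examples(rec, event_list(), stft_spec())
  expect_length(ex, 1L)
  expect_equal(dim(ex[[1]]$x), c(64L, 256L, 19L))
  expect_equal(sum(ex[[1]]$mask), 45)       # floor((6000-256)/128)+1
  expect_true(all(ex[[1]]$x[46:64, , ] == 0))
  # frame times keep the constant hop tiling into the padding
  expect_equal(diff(ex[[1]]$frame_times[, 1]), rep(1.28, 63))
})

test_that("frame labels follow the 50% window-overlap rule", {
  rec <- tiny_recording(120, 100, seed = 10)
  # event covering one whole block: all its real frames labeled 1
  ev_all <- event_list(0, 120)
  ex <- make_examples(rec, ev_all, stft_spec())
  expect_true(all(ex[[1]]$y[ex[[1]]$mask > 0] == 1))

  # event overlapping only 10% of one frame window -> frame labeled 0
  # frame 1 window is [0, 2.56); 10% overlap = [0, 0.256)
  # (min event duration aside, the rule is pure interval arithmetic)
  ev_tiny <- event_list(0, 0.256)
  ex2 <- make_examples(rec, ev_tiny, stft_spec())
  expect_equal(ex2[[1]]$y[1], 0)

  # exactly half the window inside the event -> labeled 1
  ev_half <- event_list(0, 1.28)
  ex3 <- make_examples(rec, ev_half, stft_spec())
  expect_equal(ex3[[1]]$y[1], 1)

  # a record shorter than one window yields no examples, with a warning
  short <- tiny_recording(2, 100, seed = 10)
  short$data <- short$data[, 1:100]
  expect_warning(out <- make_examples(short, event_list(), stft_spec()),
                 "shorter")
  expect_length(out, 0L)
})

test_that("the preprocessing pipeline is deterministic", {
  rec <- tiny_recording(20, 100, seed = 12)
  a <- normalize_examples(make_examples(rec, event_list(), stft_spec()))
  b <- normalize_examples(make_examples(rec, event_list(), stft_spec()))
  expect_identical(a, b)
})
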