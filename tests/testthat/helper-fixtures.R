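# shared helpers: numerical gradients, brute-force oracles, tiny fixtures

relerr <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

# brute-force direct-sum STFT with absolute sample indices in the
# exponent; the independent oracle for stft_frames()
stft_oracle <- function(x, wl, hop, h) {
  K <- (length(x) - wl) %/% hop + 1L
  out <- matrix(0i, K, wl)
  for (t in seq_len(K)) {
    tau <- ((t - 1L) * hop):((t - 1L) * hop + wl - 1L)  # absolute, 0-based
    seg <- x[tau + 1L] * h
    for (f in 0:(wl - 1L)) {
      out[t, f + 1L] <- sum(seg * exp(-2i * pi * f * tau / wl))
    }
  }
  out
}

canonical_19 <- swdnet:::CANONICAL_CHANNELS

# small white-noise recording with the 19 canonical channels
tiny_recording <- function(n_s = 10, fs = 100, seed = 1, events = NULL,
                           labels = canonical_19) {
  set.seed(seed)
  data <- matrix(rnorm(length(labels) * n_s * fs, sd = 20),
                 length(labels), n_s * fs)
  recording(data, fs, channel_labels = labels,
            annotations = if (is.null(events)) event_list() else events,
            record_id = paste0("tiny", seed))
}

# band-averaged Welch-style power spectral density
band_power <- function(x, fs, lo, hi) {
  ps <- stats::spec.pgram(x, spans = 11, plot = FALSE, taper = 0.1)
  f <- ps$freq * fs
  mean(ps$spec[f >= lo & f <= hi])
}

# tiny random feature examples for optimizer tests (shape matches the
# canonical model input)
random_examples <- function(n, seed = 1, t_frames = 64L, n_feat = 256L,
                            n_ch = 19L, pos_frac = 0.5) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    y <- as.numeric(runif(t_frames) < pos_frac)
    x <- array(rnorm(t_frames * n_feat * n_ch, sd = 0.5),
               c(t_frames, n_feat, n_ch))
    # plant a learnable signal: positive frames get a mean shift
    x[y > 0, 1:8, ] <- x[y > 0, 1:8, ] + 2
    list(x = x, y = y, mask = rep(1, t_frames),
         frame_times = cbind(start_s = (seq_len(t_frames) - 1) * 1.28,
                             end_s = (seq_len(t_frames) - 1) * 1.28 + 2.56),
         record_id = sprintf("rand%02d", i))
  })
}
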