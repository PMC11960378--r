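#' Short-time Fourier transform specification
#'
#' Window lengths of 64, 128, 256 and 512 samples correspond, at the
#' pipeline's 100 Hz working rate, to roughly 0.64-5 s of context; the
#' default 256-sample (2.56 s) window is the one that carries about 2.5 s
#' of frequency-domain context per frame. Hop defaults to half the window
#' (50% overlap). Each frame contributes 256 features: 128 log-magnitude
#' spectrogram bins concatenated with 128 raw-signal samples (the same
#' window decimated by 2).
#'
#' @param window_len Window length in samples; a power of two.
#' @param hop Hop in samples; `0 < hop <= window_len`. Default
#'   `window_len / 2`.
#' @param window_fn Taper: `"hann"` (default), `"hamming"` or `"rect"`.
#' @param n_features Feature-vector length per frame (must be 256 for the
#'   canonical 128 + 128 assembly).
#' @param n_spec_bins Number of spectrogram bins kept (default 128).
#' @return An object of class `stft_spec`.
#' @export
stft_spec <- function(window_len = 256, hop = window_len / 2,
                      window_fn = c("hann", "hamming", "rect"),
                      n_features = 256, n_spec_bins = 128) {
  window_fn <- match.arg(window_fn)
  stopifnot(window_len >= 2, hop > 0, hop <= window_len)
  if (bitwAnd(as.integer(window_len), as.integer(window_len) - 1L) != 0L) {
    stop("window_len must be a power of two", call. = FALSE)
  }
  structure(list(window_len = as.integer(window_len), hop = as.integer(hop),
                 window_fn = window_fn, n_features = as.integer(n_features),
                 n_spec_bins = as.integer(n_spec_bins)),
            class = "stft_spec")
}

taper <- function(window_fn, n) {
  k <- 0:(n - 1)
  switch(window_fn,
         hann = 0.5 - 0.5 * cos(2 * pi * k / n),
         hamming = 0.54 - 0.46 * cos(2 * pi * k / n),
         rect = rep(1, n))
}

#' Short-time Fourier transform of one channel
#'
#' Discrete realization of the windowed transform
#' `X(f, t) = sum_tau x(tau) h(tau - t hop) exp(-i 2 pi f tau / W)`,
#' with the absolute sample index `tau` in the exponent: each frame is the
#' DFT of its windowed segment times the frame's absolute phase factor
#' `exp(-i 2 pi f t hop / W)`. Frame count is
#' `floor((length - window_len) / hop) + 1`.
#'
#' @param channel_signal Numeric sample vector.
#' @param spec An [stft_spec()].
#' @param fs Sampling rate in Hz (used only for the frequency axis
#'   attribute).
#' @return Complex matrix, frames x window_len bins, with attributes
#'   `freq_hz` (bin centers) and `frame_start` (0-based sample offsets).
#' @export
stft_frames <- function(channel_signal, spec = stft_spec(), fs = 100) {
  wl <- spec$window_len
  hop <- spec$hop
  n <- length(channel_signal)
  if (n < wl) stop("signal shorter than the analysis window", call. = FALSE)
  K <- (n - wl) %/% hop + 1L
  h <- taper(spec$window_fn, wl)
  starts <- (seq_len(K) - 1L) * hop
  seg <- vapply(starts, function(s0) channel_signal[(s0 + 1L):(s0 + wl)] * h,
                numeric(wl))
  F <- stats::mvfft(seg)                      # wl x K, DFT per column
  f <- 0:(wl - 1L)
  phase <- exp(-2i * pi * outer(f, starts) / wl)
  out <- t(F * phase)                         # frames x bins
  attr(out, "freq_hz") <- f * fs / wl
  attr(out, "frame_start") <- starts
  out
}

#' Combined spectrogram + raw-signal features for a recording
#'
#' For each of the 19 channels and each analysis frame, builds the
#' 256-long feature vector: 128 log-magnitude spectrogram values
#' (`log(1 + |X|)` over bins 0-127) concatenated with 128 raw-signal
#' values (the frame's 256-sample window decimated by 2). Spectrogram and
#' raw halves use the identical window and hop. The recording is expected
#' to be band-pass filtered and at the 100 Hz working rate.
#'
#' @param rec A 19-channel [recording()].
#' @param spec An [stft_spec()].
#' @return Array frames x 256 x 19 with attribute `frame_times`
#'   (frames x 2 matrix of window start/end seconds).
#' @export
combined_features <- function(rec, spec = stft_spec()) {
  stopifnot(inherits(rec, "recording"))
  if (spec$n_features != spec$n_spec_bins + spec$window_len %/% 2L ||
      spec$n_features != 256L) {
    stop("canonical feature assembly requires n_features = 256 ",
         "(128 spectrogram bins + 128 decimated raw samples)",
         call. = FALSE)
  }
  nch <- nrow(rec$data)
  wl <- spec$window_len
  hop <- spec$hop
  n <- ncol(rec$data)
  if (n < wl) stop("recording shorter than the analysis window",
                   call. = FALSE)
  K <- (n - wl) %/% hop + 1L
  out <- array(0, c(K, spec$n_features, nch))
  starts <- (seq_len(K) - 1L) * hop
  raw_idx <- seq(1L, wl, by = 2L)
  for (ch in seq_len(nch)) {
    S <- stft_frames(rec$data[ch, ], spec, rec$fs)
    out[, 1:spec$n_spec_bins, ch] <- log1p(Mod(S[, 1:spec$n_spec_bins,
                                                 drop = FALSE]))
    seg <- vapply(starts, function(s0) rec$data[ch, s0 + raw_idx],
                  numeric(length(raw_idx)))
    out[, (spec$n_spec_bins + 1L):spec$n_features, ch] <- t(seg)
  }
  attr(out, "frame_times") <- cbind(start_s = starts / rec$fs,
                                    end_s = (starts + wl) / rec$fs)
  out
}

#' Cut a recording into fixed-length labeled feature examples
#'
#' Computes [combined_features()] and groups consecutive frames into
#' non-overlapping blocks of 64 (frames within a block still overlap
#' according to the hop), the network's input unit of shape 64 x 256 x 19.
#' A frame is labeled 1 when at least half of its analysis window lies
#' inside a seizure event. The trailing partial block is zero-padded and
#' its padded frames are masked out of loss and metrics.
#'
#' @param rec A 19-channel [recording()] at the working rate.
#' @param events Ground-truth event list; defaults to `rec$annotations`.
#' @param spec An [stft_spec()].
#' @param block_len Frames per example (64 for the canonical model input).
#' @return List of feature examples, each a list with elements `x`
#'   (array `block_len` x 256 x 19), `y` (binary labels), `mask`
#'   (1 = real frame, 0 = padding), `frame_times` (matrix), and
#'   `record_id`. Empty list (with a warning) when the record is shorter
#'   than one analysis window.
#' @export
make_examples <- function(rec, events = rec$annotations, spec = stft_spec(),
                          block_len = 64L) {
  stopifnot(inherits(rec, "recording"))
  events <- as_event_list(events)
  if (ncol(rec$data) < spec$window_len) {
    warning("record shorter than one analysis window; no examples")
    return(list())
  }
  feats <- combined_features(rec, spec)
  ft <- attr(feats, "frame_times")
  K <- nrow(ft)
  win_dur <- spec$window_len / rec$fs
  labels <- vapply(seq_len(K), function(i) {
    ov <- interval_overlap(ft[i, 1], ft[i, 2], events)
    as.numeric(sum(ov) >= 0.5 * win_dur)
  }, numeric(1))
  n_blocks <- ceiling(K / block_len)
  out <- vector("list", n_blocks)
  hop_s <- spec$hop / rec$fs
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1L) * block_len + 1L):min(b * block_len, K)
    x <- array(0, c(block_len, dim(feats)[2], dim(feats)[3]))
    x[seq_along(idx), , ] <- feats[idx, , , drop = FALSE]
    y <- numeric(block_len)
    y[seq_along(idx)] <- labels[idx]
    mask <- numeric(block_len)
    mask[seq_along(idx)] <- 1
    # padded frames keep the tiling: times continue at the constant hop
    t0 <- ft[idx[1], 1]
    times <- cbind(start_s = t0 + (seq_len(block_len) - 1L) * hop_s,
                   end_s = t0 + (seq_len(block_len) - 1L) * hop_s + win_dur)
    out[[b]] <- list(x = x, y = y, mask = mask, frame_times = times,
                     record_id = rec$record_id)
  }
  out
}

#' Normalize a stream of feature examples
#'
#' Per record and channel, the raw-signal half of the feature vector is
#' z-scored (mean 0, sd 1 over all unmasked frames of that record); the
#' spectrogram half is divided by the record's global log-magnitude
#' standard deviation. Degenerate (constant) channels map to all-zero
#' features. Padded frames stay zero. This removes inter-device amplitude
#' scale: multiplying a record's microvolt values by a constant leaves the
#' normalized output unchanged.
#'
#' @param examples List of feature examples (see [make_examples()]),
#'   possibly spanning several records.
#' @param spec The [stft_spec()] used to build them.
#' @return The normalized example list.
#' @export
normalize_examples <- function(examples, spec = stft_spec()) {
  if (length(examples) == 0L) return(examples)
  nb <- spec$n_spec_bins
  nf <- spec$n_features
  ids <- vapply(examples, function(e) e$record_id, "")
  for (rid in unique(ids)) {
    ex_i <- which(ids == rid)
    # gather unmasked frames: frames x features x channels
    gather <- lapply(ex_i, function(i) {
      e <- examples[[i]]
      e$x[e$mask > 0, , , drop = FALSE]
    })
    allx <- do.call(abind_frames, gather)
    spec_sd <- sd(allx[, 1:nb, ])
    if (!is.finite(spec_sd) || spec_sd < 1e-12) spec_sd <- NA
    nch <- dim(allx)[3]
    raw_mu <- raw_sd <- numeric(nch)
    for (ch in seq_len(nch)) {
      v <- allx[, (nb + 1L):nf, ch]
      raw_mu[ch] <- mean(v)
      raw_sd[ch] <- sd(as.vector(v))
    }
    degenerate_raw <- !is.finite(raw_sd) | raw_sd < 1e-12
    if (any(degenerate_raw) || is.na(spec_sd)) {
      message("normalize_examples: degenerate (constant) features in record ",
              rid, " mapped to zeros")
    }
    for (i in ex_i) {
      e <- examples[[i]]
      live <- e$mask > 0
      if (is.na(spec_sd)) {
        e$x[live, 1:nb, ] <- 0
      } else {
        e$x[live, 1:nb, ] <- e$x[live, 1:nb, , drop = FALSE] / spec_sd
      }
      for (ch in seq_len(nch)) {
        if (degenerate_raw[ch]) {
          e$x[live, (nb + 1L):nf, ch] <- 0
        } else {
          e$x[live, (nb + 1L):nf, ch] <-
            (e$x[live, (nb + 1L):nf, ch, drop = FALSE] - raw_mu[ch]) /
            raw_sd[ch]
        }
      }
      examples[[i]] <- e
    }
  }
  examples
}

# bind a list of frames x features x channels arrays along frames
abind_frames <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) dim(p)[1] > 0, TRUE)]
  if (length(parts) == 1L) return(parts[[1]])
  d <- dim(parts[[1]])
  total <- sum(vapply(parts, function(p) dim(p)[1], 0L))
  out <- array(0, c(total, d[2], d[3]))
  at <- 0L
  for (p in parts) {
    out[at + seq_len(dim(p)[1]), , ] <- p
    at <- at + dim(p)[1]
  }
  out
}

#' Persist a feature-example stream
#'
#' Writes the logical container layout `/examples`, `/labels`, `/mask`,
#' `/frame_times`, `/record_ids` as a serialized list plus a JSON manifest
#' next to it.
#'
#' @param examples List of feature examples.
#' @param path Output `.rds` path.
#' @return `path`, invisibly.
#' @export
write_examples <- function(examples, path) {
  container <- list(
    examples = lapply(examples, `[[`, "x"),
    labels = lapply(examples, `[[`, "y"),
    mask = lapply(examples, `[[`, "mask"),
    frame_times = lapply(examples, `[[`, "frame_times"),
    record_ids = vapply(examples, `[[`, "", "record_id")
  )
  saveRDS(container, path)
  manifest <- list(n_examples = length(examples),
                   shape = if (length(examples)) dim(examples[[1]]$x)
                   else integer(),
                   records = unique(container$record_ids))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Load a feature-example stream written by [write_examples()]
#' @param path The `.rds` path.
#' @return List of feature examples.
#' @export
read_examples <- function(path) {
  container <- readRDS(path)
  lapply(seq_along(container$examples), function(i) {
    list(x = container$examples[[i]], y = container$labels[[i]],
         mask = container$mask[[i]],
         frame_times = container$frame_times[[i]],
         record_id = container$record_ids[[i]])
  })
}
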