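#' Synthetic absence-EEG configuration
#'
#' Defines the statistical structure of generated recordings: ongoing
#' background activity (1/f noise plus a posterior-dominant alpha rhythm),
#' generalized 3 Hz spike-and-slow-wave bursts with frontal/central
#' amplitude dominance, common scalp artifacts (blink, EMG, ECG), and the
#' severe class imbalance of long-term clinical EEG (seizure time about
#' 1.08% of total by default). All randomness flows from the single `seed`.
#'
#' @param duration_s Record duration in seconds.
#' @param fs Sampling rate in Hz; default 500 so the downsampling path is
#'   exercised.
#' @param n_records Number of records (used by corpus helpers).
#' @param seizure_fraction Target fraction of seizure time; default 0.0108.
#'   The `"balanced"` preset (see [synth_config_balanced()]) uses 0.2.
#' @param swd_freq_hz Spike-wave repetition rate in Hz.
#' @param event_dur_range_s Min/max seizure duration in seconds.
#' @param frontal_gain Amplitude multiplier on fp1, fp2, f3, f4, fz, cz.
#' @param background_alpha_hz Posterior rhythm frequency in Hz.
#' @param alpha_uv Posterior alpha amplitude in microvolts (smaller
#'   elsewhere).
#' @param swd_spike_uv,swd_wave_uv Spike and slow-wave amplitudes in
#'   microvolts (pre frontal gain).
#' @param artifact_rates Named per-minute rates for `blink`, `emg`, `ecg`
#'   (`ecg` is 0/1: a continuous faint trace).
#' @param noise_scale Background 1/f noise standard deviation in
#'   microvolts.
#' @param min_gap_s Minimum separation between planted events (and from
#'   record edges).
#' @param seed Integer seed fixing all randomness.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(duration_s = 600, fs = 500, n_records = 1,
                         seizure_fraction = 0.0108, swd_freq_hz = 3,
                         event_dur_range_s = c(4, 15), frontal_gain = 1.5,
                         background_alpha_hz = 9, alpha_uv = 8,
                         swd_spike_uv = 120, swd_wave_uv = 80,
                         artifact_rates = c(blink = 4, emg = 2, ecg = 1),
                         noise_scale = 15, min_gap_s = 5, seed = 1L) {
  stopifnot(duration_s > 0, fs > 0, n_records >= 1,
            seizure_fraction >= 0, seizure_fraction < 0.5,
            length(event_dur_range_s) == 2,
            all(event_dur_range_s > 0),
            event_dur_range_s[1] <= event_dur_range_s[2],
            swd_freq_hz > 0, noise_scale > 0)
  structure(list(duration_s = duration_s, fs = fs, n_records = n_records,
                 seizure_fraction = seizure_fraction,
                 swd_freq_hz = swd_freq_hz,
                 event_dur_range_s = event_dur_range_s,
                 frontal_gain = frontal_gain,
                 background_alpha_hz = background_alpha_hz,
                 alpha_uv = alpha_uv, swd_spike_uv = swd_spike_uv,
                 swd_wave_uv = swd_wave_uv, artifact_rates = artifact_rates,
                 noise_scale = noise_scale, min_gap_s = min_gap_s,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Balanced synthetic preset
#'
#' Same generator with seizure fraction 0.2: a deliberately easy,
#' class-balanced regime for fast CPU training exercises.
#'
#' @param ... Overrides passed to [synth_config()].
#' @return A `synth_config`.
#' @export
synth_config_balanced <- function(...) {
  args <- list(...)
  args$seizure_fraction <- args$seizure_fraction %||% 0.2
  do.call(synth_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

FRONTAL_CENTRAL <- c("fp1", "fp2", "f3", "f4", "fz", "cz")
POSTERIOR <- c("o1", "o2", "p3", "p4")
TEMPORAL <- c("f7", "f8", "t3", "t4", "t5", "t6")

# 1/f-shaped Gaussian noise of length n at rate fs, unit variance
pink_noise <- function(n, fs) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                 # two-sided frequency magnitude
  gain <- 1 / sqrt(pmax(f, 0.5))       # flatten below 0.5 Hz
  gain[1] <- 0                         # zero mean
  x <- Re(stats::fft(X * gain, inverse = TRUE)) / n
  x / sd(x)
}

#' Generate background EEG
#'
#' 19 x `n_samples` matrix of ongoing activity: per-channel 1/f ("pink")
#' noise scaled to `noise_scale` microvolts plus an amplitude-modulated
#' alpha oscillation, posterior-dominant (larger on o1, o2, p3, p4).
#' Zero-mean by construction; typical channel amplitudes sit in the
#' 10-50 microvolt range.
#'
#' @param config A [synth_config()].
#' @param n_samples Number of samples per channel.
#' @return 19 x `n_samples` numeric matrix (rownames = canonical
#'   channels).
#' @export
generate_background <- function(config, n_samples) {
  stopifnot(n_samples > 0)
  fs <- config$fs
  t <- (seq_len(n_samples) - 1) / fs
  out <- matrix(0, length(CANONICAL_CHANNELS), n_samples,
                dimnames = list(CANONICAL_CHANNELS, NULL))
  # slow common modulation of alpha power
  env_raw <- pink_noise(n_samples, fs)
  env <- stats::filter(abs(env_raw), rep(1 / (2 * fs), 2 * fs),
                       circular = TRUE)
  env <- as.numeric(env) / max(mean(env), 1e-12)
  alpha_phase <- stats::runif(1, 0, 2 * pi)
  alpha <- sin(2 * pi * config$background_alpha_hz * t + alpha_phase) * env
  for (ch in seq_len(nrow(out))) {
    amp <- if (CANONICAL_CHANNELS[ch] %in% POSTERIOR) config$alpha_uv
    else config$alpha_uv / 4
    out[ch, ] <- config$noise_scale * pink_noise(n_samples, fs) + amp * alpha
  }
  out
}

#' Generate one generalized spike-and-slow-wave burst
#'
#' Repeated spike-wave complexes at `swd_freq_hz` (default 3 Hz): a sharp
#' positive Gaussian spike (~70 ms) followed by a slow half-sine
#' (~260 ms), synchronous across all 19 channels, with amplitude scaled by
#' `frontal_gain` on the frontal/central channels. Burst edges are tapered
#' over half a complex so onsets are not step discontinuities.
#'
#' @param config A [synth_config()].
#' @param dur_s Burst duration in seconds (within `event_dur_range_s`).
#' @return 19 x `round(dur_s * fs)` numeric matrix.
#' @export
generate_swd_burst <- function(config, dur_s) {
  stopifnot(dur_s >= config$event_dur_range_s[1] - 1e-9,
            dur_s <= config$event_dur_range_s[2] + 1e-9)
  fs <- config$fs
  n <- round(dur_s * fs)
  t <- (seq_len(n) - 1) / fs
  period <- 1 / config$swd_freq_hz
  tau <- t %% period                    # position inside the complex
  spike_w <- 0.070
  wave_w <- 0.260
  spike <- config$swd_spike_uv *
    exp(-0.5 * ((tau - spike_w / 2) / (spike_w / 4))^2)
  in_wave <- tau >= spike_w & tau < spike_w + wave_w
  wave <- numeric(n)
  wave[in_wave] <- -config$swd_wave_uv *
    sin(pi * (tau[in_wave] - spike_w) / wave_w)
  shape <- spike + wave
  # taper edges over half a complex
  ramp_n <- max(2L, round(period / 2 * fs))
  ramp <- rep(1, n)
  ramp[seq_len(min(ramp_n, n))] <- seq(0, 1, length.out = min(ramp_n, n))
  ramp[n:max(1L, n - ramp_n + 1L)] <- seq(0, 1, length.out = min(ramp_n, n))
  shape <- shape * ramp
  gain <- ifelse(CANONICAL_CHANNELS %in% FRONTAL_CENTRAL,
                 config$frontal_gain, 1)
  # mild per-channel amplitude variation, synchronous waveform
  jitter <- 1 + 0.05 * stats::rnorm(length(CANONICAL_CHANNELS))
  out <- outer(gain * jitter, shape)
  rownames(out) <- CANONICAL_CHANNELS
  out
}

#' Inject blink, EMG and ECG artifacts into a background matrix
#'
#' Blinks: frontal-dominant biphasic transients (~0.3 s, ~100 uV on fp1/
#' fp2). EMG: broadband 25-45 Hz bursts (0.5-2 s) on temporal channels.
#' ECG: a faint continuous ~1.2 Hz spike train on all channels. Injected
#' intervals are logged in the `artifact_log` attribute (a tibble with
#' `type`, `start_s`, `end_s`). With all rates zero the input is returned
#' unchanged.
#'
#' @param background 19 x n matrix from [generate_background()].
#' @param config A [synth_config()].
#' @return The contaminated matrix with attribute `artifact_log`.
#' @export
inject_artifacts <- function(background, config) {
  fs <- config$fs
  n <- ncol(background)
  dur_min <- n / fs / 60
  rates <- config$artifact_rates
  log <- tibble::tibble(type = character(), start_s = numeric(),
                        end_s = numeric())
  out <- background
  blink_gain <- ifelse(CANONICAL_CHANNELS %in% c("fp1", "fp2"), 1,
                       ifelse(CANONICAL_CHANNELS %in% c("f3", "f4", "f7",
                                                        "f8"), 0.4, 0.05))
  n_blink <- stats::rpois(1, (rates[["blink"]] %||% 0) * dur_min)
  blink_n <- round(0.3 * fs)
  if (n_blink > 0 && n > blink_n + 2) {
    tt <- seq(0, 1, length.out = blink_n)
    # biphasic: dominant positive deflection with a small rebound
    shape <- 100 * exp(-0.5 * ((tt - 0.45) / 0.18)^2) -
      30 * exp(-0.5 * ((tt - 0.8) / 0.12)^2)
    for (i in seq_len(n_blink)) {
      s0 <- sample.int(n - blink_n, 1)
      idx <- s0:(s0 + blink_n - 1L)
      out[, idx] <- out[, idx] + outer(blink_gain, shape)
      log <- dplyr::bind_rows(log, tibble::tibble(
        type = "blink", start_s = (s0 - 1) / fs,
        end_s = (s0 - 1 + blink_n) / fs))
    }
  }
  emg_gain <- ifelse(CANONICAL_CHANNELS %in% TEMPORAL, 1, 0.05)
  n_emg <- stats::rpois(1, (rates[["emg"]] %||% 0) * dur_min)
  if (n_emg > 0) {
    for (i in seq_len(n_emg)) {
      len <- round(stats::runif(1, 0.5, 2) * fs)
      if (len + 2 >= n) next
      s0 <- sample.int(n - len, 1)
      idx <- s0:(s0 + len - 1L)
      burst <- band_noise(len, fs, 25, 45) * 25
      out[, idx] <- out[, idx] + outer(emg_gain, burst)
      log <- dplyr::bind_rows(log, tibble::tibble(
        type = "emg", start_s = (s0 - 1) / fs, end_s = (s0 - 1 + len) / fs))
    }
  }
  if ((rates[["ecg"]] %||% 0) > 0) {
    t <- (seq_len(n) - 1) / fs
    rr <- 1 / 1.2                        # ~72 bpm
    phase <- (t %% rr) / rr
    qrs <- 3 * exp(-0.5 * ((phase - 0.2) / 0.015)^2)
    out <- out + matrix(qrs, nrow(out), n, byrow = TRUE)
    log <- dplyr::bind_rows(log, tibble::tibble(
      type = "ecg", start_s = 0, end_s = n / fs))
  }
  attr(out, "artifact_log") <- log
  out
}

# Gaussian noise band-limited to [lo, hi] Hz, unit-ish variance
band_noise <- function(n, fs, lo, hi) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)
  X[f < lo | f > hi] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- sd(x)
  if (s < 1e-12) x else x / s
}

# draw event durations totalling ~ target_s (within -20%/+20%)
draw_event_durations <- function(target_s, range_s) {
  if (target_s < range_s[1]) return(numeric())
  durs <- numeric()
  total <- 0
  while (total < target_s) {
    d <- stats::runif(1, range_s[1], range_s[2])
    if (total + d > target_s) {
      rem <- target_s - total
      if (rem >= range_s[1]) {
        d <- rem
      } else if (total >= 0.8 * target_s) {
        break
      } else {
        d <- range_s[1]
      }
    }
    durs <- c(durs, d)
    total <- total + d
  }
  durs
}

# place events of given durations uniformly at random, non-overlapping,
# separated by >= gap_s from each other and the record edges
place_events <- function(durs, duration_s, gap_s) {
  placed_start <- numeric()
  placed_end <- numeric()
  for (d in durs) {
    ok <- FALSE
    for (try in seq_len(2000L)) {
      s0 <- stats::runif(1, gap_s, duration_s - gap_s - d)
      if (length(placed_start) == 0L ||
          all(s0 - gap_s >= placed_end | s0 + d + gap_s <= placed_start)) {
        placed_start <- c(placed_start, s0)
        placed_end <- c(placed_end, s0 + d)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("could not place events: seizure fraction too high for the ",
           "record duration and separation constraint", call. = FALSE)
    }
  }
  ord <- order(placed_start)
  cbind(start_s = placed_start[ord], end_s = placed_end[ord])
}

#' Simulate an annotated absence-epilepsy recording
#'
#' Background plus artifacts, with spike-wave bursts planted at uniformly
#' random non-overlapping times separated by at least `min_gap_s`. The
#' returned annotations are the exact planted intervals; their total
#' duration is within +/-20% of `seizure_fraction * duration_s` (or
#' exactly zero events when that target is below the minimum event
#' duration).
#'
#' @param config A [synth_config()].
#' @param record_id Identifier for the generated record.
#' @return A [recording()]; the planted events are in `$annotations` and
#'   the artifact log in `attr(, "artifact_log")`.
#' @export
simulate_recording <- function(config, record_id = "synthetic") {
  stopifnot(inherits(config, "synth_config"))
  target_s <- config$seizure_fraction * config$duration_s
  if (target_s >= config$event_dur_range_s[1] &&
      config$duration_s < target_s + 2 * config$min_gap_s) {
    stop("infeasible configuration: duration too short for the requested ",
         "seizure fraction", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()), add = TRUE)
  set.seed(config$seed)
  n <- round(config$duration_s * config$fs)
  bg <- generate_background(config, n)
  x <- inject_artifacts(bg, config)
  alog <- attr(x, "artifact_log")
  durs <- draw_event_durations(target_s, config$event_dur_range_s)
  if (length(durs) > 0L) {
    pos <- place_events(durs, config$duration_s, config$min_gap_s)
    for (i in seq_len(nrow(pos))) {
      burst <- generate_swd_burst(config, pos[i, 2] - pos[i, 1])
      s0 <- round(pos[i, 1] * config$fs) + 1L
      idx <- s0:(s0 + ncol(burst) - 1L)
      x[, idx] <- x[, idx] + burst
    }
    events <- event_list(pos[, 1], pos[, 2])
  } else {
    events <- event_list()
  }
  rec <- recording(x, config$fs, channel_labels = CANONICAL_CHANNELS,
                   annotations = events, record_id = record_id)
  attr(rec, "artifact_log") <- alog
  rec
}

#' Simulate a corpus of recordings
#'
#' Generates `config$n_records` recordings with per-record seeds derived
#' deterministically from `config$seed`.
#'
#' @param config A [synth_config()].
#' @param id_prefix Record-id prefix.
#' @return List of [recording()] objects.
#' @export
simulate_corpus <- function(config, id_prefix = "synthetic") {
  lapply(seq_len(config$n_records), function(i) {
    cfg_i <- config
    cfg_i$seed <- (config$seed * 1009L + i * 7919L) %% 2147483647L
    simulate_recording(cfg_i, record_id = sprintf("%s_%03d", id_prefix, i))
  })
}
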