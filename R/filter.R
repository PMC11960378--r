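#' Band-pass filter specification
#'
#' Defaults follow the detection pipeline's design: an order-12 Butterworth
#' band-pass with half-power edges at 0.16 Hz and 35 Hz, removing slow
#' drift, high-frequency EMG content and 50 Hz mains interference. "Order
#' 12" is the total band-pass order (a 6-pole low-pass prototype, giving 6
#' pole pairs after the band transform). The default application mode is
#' zero-phase (forward-backward), which doubles the effective attenuation
#' and leaves event boundaries undelayed.
#'
#' @param low_cut_hz Lower half-power edge in Hz.
#' @param high_cut_hz Upper half-power edge in Hz.
#' @param order Total band-pass order; must be even.
#' @param application_mode `"zero-phase"` (default) or `"forward"`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut_hz = 0.16, high_cut_hz = 35, order = 12,
                        application_mode = c("zero-phase", "forward")) {
  application_mode <- match.arg(application_mode)
  stopifnot(low_cut_hz > 0, high_cut_hz > low_cut_hz,
            order >= 2, order %% 2 == 0)
  structure(list(low_cut_hz = low_cut_hz, high_cut_hz = high_cut_hz,
                 order = order, design = "butterworth-bandpass",
                 application_mode = application_mode),
            class = "filter_spec")
}

#' Design Butterworth band-pass second-order sections
#'
#' Designs the analog Butterworth low-pass prototype analytically, applies
#' the low-pass-to-band-pass transform and the bilinear transform (with
#' frequency prewarping, via the `signal` package), and pairs the result
#' into cascaded second-order sections. Every section carries zeros at
#' z = +1 and z = -1; the overall gain is distributed evenly across
#' sections. A high-order band-pass in direct (b, a) form is numerically
#' unstable; the SOS cascade is not.
#'
#' @param spec A [filter_spec()].
#' @param fs Sampling rate in Hz; requires `high_cut_hz < fs/2`.
#' @return A `sections x 6` matrix with columns `b0 b1 b2 a0 a1 a2`.
#' @export
butter_sos <- function(spec, fs) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$high_cut_hz >= fs / 2) {
    stop("high_cut_hz must be below the Nyquist frequency fs/2",
         call. = FALSE)
  }
  n <- spec$order / 2           # analog low-pass prototype order
  # prototype: unit-cutoff all-pole Butterworth
  k <- seq_len(n)
  proto_poles <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # prewarped band edges (bilinear with T = 2 maps W_analog = tan(pi f / fs))
  W <- tan(pi * c(spec$low_cut_hz, spec$high_cut_hz) / fs)
  st <- signal::sftrans(Sz = numeric(0), Sp = proto_poles, Sg = 1,
                        W = W, stop = FALSE)
  dt <- signal::bilinear(Sz = st$zero, Sp = st$pole, Sg = st$gain, T = 2)
  poles <- dt$pole
  if (any(Mod(poles) >= 1)) {
    stop("unstable filter realization: pole modulus >= 1", call. = FALSE)
  }
  # keep one pole of each conjugate pair, sorted by modulus (closest to the
  # unit circle last, so early sections are the best conditioned)
  upper <- poles[Im(poles) > 0]
  if (length(upper) != n) {
    # fall back: group conjugates explicitly
    upper <- poles[!duplicated(round(Mod(poles), 12) +
                                 1i * round(abs(Im(poles)), 12))][seq_len(n)]
  }
  upper <- upper[order(Mod(upper))]
  gsec <- abs(Re(dt$gain))^(1 / n)
  sos <- matrix(0, n, 6)
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  for (i in seq_len(n)) {
    p <- upper[i]
    sos[i, ] <- c(gsec * c(1, 0, -1), 1, -2 * Re(p), Mod(p)^2)
  }
  if (Re(dt$gain) < 0) sos[1, 1:3] <- -sos[1, 1:3]
  sos
}

#' Frequency response of an SOS cascade
#'
#' @param sos Second-order-section matrix from [butter_sos()].
#' @param f Frequencies in Hz at which to evaluate.
#' @param fs Sampling rate in Hz.
#' @return Complex response values, one per frequency.
#' @export
sos_freqz <- function(sos, f, fs) {
  w <- 2 * pi * f / fs
  z1 <- exp(-1i * w)
  z2 <- exp(-2i * w)
  H <- rep(1 + 0i, length(f))
  for (i in seq_len(nrow(sos))) {
    H <- H * (sos[i, 1] + sos[i, 2] * z1 + sos[i, 3] * z2) /
      (sos[i, 4] + sos[i, 5] * z1 + sos[i, 6] * z2)
  }
  H
}

# steady-state initial conditions for one direct-form-II-transposed section,
# for unit constant input (lfilter_zi construction)
section_zi <- function(b, a) {
  A <- rbind(c(-a[2], 1), c(-a[3], 0))
  B <- c(b[2] - b[1] * a[2], b[3] - b[1] * a[3])
  solve(diag(2) - A, B)
}

#' Filter a signal through an SOS cascade
#'
#' Applies the cascade once (forward) with steady-state initial conditions
#' matched to the first sample, which suppresses the start-up step
#' transient.
#'
#' @param sos SOS matrix.
#' @param x Numeric vector.
#' @return Filtered vector, same length.
#' @export
sosfilt <- function(sos, x) {
  zi <- t(vapply(seq_len(nrow(sos)),
                 function(i) section_zi(sos[i, 1:3], sos[i, 4:6]),
                 numeric(2)))
  # chain the per-section DC gains so each section starts at its own
  # steady state for the (already filtered) first input value
  x0 <- x[1]
  zmat <- matrix(0, nrow(sos), 2)
  for (i in seq_len(nrow(sos))) {
    zmat[i, ] <- zi[i, ] * x0
    dc <- sum(sos[i, 1:3]) / sum(sos[i, 4:6])
    x0 <- x0 * dc
  }
  sosfilt_run(sos, x, zmat)
}

#' Zero-phase filtering through an SOS cascade
#'
#' Forward-backward application with odd-reflection edge padding, giving
#' squared magnitude response and zero group delay.
#'
#' @param sos SOS matrix.
#' @param x Numeric vector.
#' @param padlen Reflection pad length in samples; `NULL` picks
#'   `min(length(x) - 1, 3 * transient)` where the transient length is
#'   estimated from the slowest section pole.
#' @return Filtered vector, same length as `x`.
#' @export
sos_filtfilt <- function(sos, x, padlen = NULL) {
  n <- length(x)
  if (is.null(padlen)) {
    rmax <- max(apply(sos, 1L, function(s) {
      max(Mod(polyroot(c(s[6], s[5], s[4]))))
    }))
    padlen <- min(n - 1L, as.integer(ceiling(3 / max(1e-6, 1 - rmax))))
  }
  padlen <- max(0L, min(n - 1L, as.integer(padlen)))
  if (padlen > 0L) {
    pre <- 2 * x[1] - x[(padlen + 1L):2L]
    post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
    ext <- c(pre, x, post)
  } else ext <- x
  y <- sosfilt(sos, ext)
  y <- rev(sosfilt(sos, rev(y)))
  if (padlen > 0L) y[(padlen + 1L):(padlen + n)] else y
}

#' Band-pass filter a recording
#'
#' Filters every channel with the order-12 Butterworth band-pass described
#' by `spec`, realized as cascaded second-order sections. In the default
#' zero-phase mode the cascade is applied forward and backward, so the
#' effective attenuation is doubled and no group delay is introduced.
#'
#' @param rec A [recording()].
#' @param spec A [filter_spec()].
#' @return The filtered [recording()].
#' @export
bandpass_filter <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "recording"), inherits(spec, "filter_spec"))
  sos <- butter_sos(spec, rec$fs)
  out <- rec$data
  for (ch in seq_len(nrow(out))) {
    out[ch, ] <- if (spec$application_mode == "zero-phase") {
      sos_filtfilt(sos, rec$data[ch, ])
    } else {
      sosfilt(sos, rec$data[ch, ])
    }
  }
  recording(out, rec$fs, channel_labels = rec$channel_labels,
            annotations = rec$annotations, record_id = rec$record_id)
}
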