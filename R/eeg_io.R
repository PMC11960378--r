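#' @useDynLib swdnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom stats fft rnorm runif sd predict
NULL

# the 19 canonical 10-20 channels, fixed pipeline order
CANONICAL_CHANNELS <- c("fp1", "fp2", "f3", "f4", "c3", "c4", "p3", "p4",
                        "o1", "o2", "f7", "f8", "t3", "t4", "t5", "t6",
                        "fz", "cz", "pz")

# modern 10-20 names -> legacy names used by the canonical list
MODERN_ALIASES <- c(t7 = "t3", t8 = "t4", p7 = "t5", p8 = "t6")

#' Canonicalize an EEG channel label
#'
#' Case-insensitive mapping of a raw channel label onto one of the 19
#' canonical 10-20 names (`fp1 ... pz`). Strips a leading `"EEG "` prefix
#' and `-Ref`/`-REF`/`-LE` reference suffixes, and maps the modern temporal/
#' posterior names onto their legacy equivalents (T7->T3, T8->T4, P7->T5,
#' P8->T6). Labels that resolve to none of the 19 names return `NA`.
#'
#' @param raw_label Character vector of raw labels.
#' @return Character vector of canonical names, `NA` where unmatched.
#' @examples
#' canonicalize_label(c("EEG Fp1-Ref", "T7", "ECG"))
#' @export
canonicalize_label <- function(raw_label) {
  x <- tolower(trimws(as.character(raw_label)))
  x <- sub("^eeg\\s+", "", x)
  x <- sub("-(ref|le)$", "", x)
  x <- trimws(x)
  hit <- !is.na(match(x, names(MODERN_ALIASES)))
  x[hit] <- MODERN_ALIASES[x[hit]]
  x[!(x %in% CANONICAL_CHANNELS)] <- NA_character_
  x
}

#' Select the 19 canonical channels of a recording
#'
#' Resolves every row label via [canonicalize_label()] and returns the
#' recording restricted to the 19 canonical 10-20 channels in the fixed
#' order `fp1, fp2, f3, f4, c3, c4, p3, p4, o1, o2, f7, f8, t3, t4, t5,
#' t6, fz, cz, pz`. Non-canonical channels (ECG, reference electrodes, ...)
#' are dropped. Missing or ambiguously duplicated canonical channels are
#' errors, never silently resolved.
#'
#' @param rec A [recording()].
#' @return A 19-channel [recording()] with canonical labels.
#' @export
select_channels <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  canon <- canonicalize_label(rec$channel_labels)
  idx <- integer(length(CANONICAL_CHANNELS))
  for (i in seq_along(CANONICAL_CHANNELS)) {
    hits <- which(canon == CANONICAL_CHANNELS[i])
    if (length(hits) == 0L) {
      stop("missing canonical channel: ", CANONICAL_CHANNELS[i],
           call. = FALSE)
    }
    if (length(hits) > 1L) {
      stop("ambiguous channel resolution: labels ",
           paste(sprintf("'%s'", rec$channel_labels[hits]), collapse = ", "),
           " all map to ", CANONICAL_CHANNELS[i], call. = FALSE)
    }
    idx[i] <- hits
  }
  recording(rec$data[idx, , drop = FALSE], rec$fs,
            channel_labels = CANONICAL_CHANNELS,
            annotations = rec$annotations, record_id = rec$record_id)
}

#' Resample a recording to a new sampling rate
#'
#' Fourier-domain resampling: each channel is transformed, its spectrum
#' truncated (down) or zero-padded (up) at the new Nyquist frequency, and
#' inverted, which is inherently anti-aliased and preserves in-band
#' sinusoid amplitude to well under 1%. The new sample count is
#' `round(samples * target_fs / fs)`. Annotations are in seconds and are
#' carried over unchanged.
#'
#' @param rec A [recording()].
#' @param target_fs Target sampling rate in Hz (> 0).
#' @return A [recording()] at `target_fs`.
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "recording"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0) {
    stop("target_fs must be a single positive number", call. = FALSE)
  }
  if (abs(target_fs - rec$fs) < 1e-12) return(rec)
  n <- ncol(rec$data)
  m <- as.integer(round(n * target_fs / rec$fs))
  out <- matrix(0, nrow(rec$data), m)
  for (ch in seq_len(nrow(rec$data))) {
    out[ch, ] <- fft_resample(rec$data[ch, ], m)
  }
  recording(out, target_fs, channel_labels = rec$channel_labels,
            annotations = rec$annotations, record_id = rec$record_id)
}

# Fourier resampling of one real vector to length m (scipy-style spectrum
# truncation/padding with Nyquist-bin splitting).
fft_resample <- function(x, m) {
  n <- length(x)
  if (m == n) return(x)
  X <- stats::fft(x)
  Y <- complex(m)
  nmin <- min(n, m)
  half <- nmin %/% 2L
  Y[1:(half + 1L)] <- X[1:(half + 1L)]
  if (half >= 1L) {
    Y[(m - half + 1L):m] <- X[(n - half + 1L):n]
  }
  if (nmin %% 2L == 0L) {
    if (m < n) {
      # fold the old Nyquist energy into the shared bin
      Y[half + 1L] <- X[half + 1L] + X[n - half + 1L]
    } else {
      # split the old Nyquist bin symmetrically
      Y[half + 1L] <- X[half + 1L] / 2
      Y[m - half + 1L] <- Y[half + 1L]
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

# ---------------------------------------------------------------------------
# EDF reading and writing
#
# EDF is a fixed-width ASCII header (256 bytes + 256 per signal) followed by
# data records of little-endian int16 samples, scaled channel-wise between a
# digital and a physical range. EDF+ stores annotations in a reserved "EDF
# Annotations" signal as time-stamped ASCII lists (TALs).
# ---------------------------------------------------------------------------

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = width - 2L)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Writes standard EDF (16-bit) with one-second data records; the final
#' record is zero-padded when the record length is not a whole number of
#' seconds. Annotations are written to a sidecar CSV
#' (`<path minus extension>_events.csv` with columns `start_s,end_s,label`)
#' and, when `edfplus_annotations = TRUE`, also to an EDF+ annotation
#' signal inside the file.
#'
#' @param rec A [recording()]; `fs` must be a whole number.
#' @param path Output file path.
#' @param edfplus_annotations Also embed events as an EDF+ TAL channel.
#' @param sidecar Write the sidecar CSV (default TRUE).
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path, edfplus_annotations = FALSE,
                                sidecar = TRUE) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(round(fs))
  nch <- nrow(rec$data)
  n <- ncol(rec$data)
  n_rec <- as.integer(ceiling(n / fs))
  # physical scaling per channel
  pmax_v <- apply(abs(rec$data), 1L, max)
  pmax_v <- pmax(pmax_v, 1) * 1.0001
  tal_bytes <- 0L
  tal_chunks <- NULL
  if (edfplus_annotations) {
    ev <- rec$annotations
    tals <- character(n_rec)
    for (r in seq_len(n_rec)) {
      # record timestamp TAL, NUL-terminated
      tals[r] <- sprintf("+%g\x14\x14\x01", r - 1L)
    }
    if (nrow(ev) > 0L) {
      body <- paste0(vapply(seq_len(nrow(ev)), function(i) {
        sprintf("+%g\x15%g\x14%s\x14\x01", ev$start_s[i],
                ev$end_s[i] - ev$start_s[i], ev$label[i])
      }, character(1)), collapse = "")
      tals[1L] <- paste0(tals[1L], body)
    }
    tal_bytes <- 2L * ceiling(max(nchar(tals, type = "bytes") + 1L) / 2L)
    tal_chunks <- tals
  }
  ns <- nch + as.integer(edfplus_annotations)
  header_bytes <- 256L + 256L * ns
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(edf_pad("0", 8L))
  wr(edf_pad(rec$record_id, 80L))
  wr(edf_pad("Startdate X X X X", 80L))
  wr(edf_pad("01.01.00", 8L))
  wr(edf_pad("00.00.00", 8L))
  wr(edf_pad(header_bytes, 8L))
  wr(edf_pad(if (edfplus_annotations) "EDF+C" else "", 44L))
  wr(edf_pad(n_rec, 8L))
  wr(edf_pad(1, 8L))
  wr(edf_pad(ns, 4L))
  labels <- rec$channel_labels
  wr(paste0(vapply(labels, edf_pad, "", width = 16L), collapse = ""))
  if (edfplus_annotations) wr(edf_pad("EDF Annotations", 16L))
  wr(strrep(" ", 80L * ns))                          # transducer
  wr(paste0(c(rep(edf_pad("uV", 8L), nch),
              rep(edf_pad("", 8L), ns - nch)), collapse = ""))
  wr(paste0(c(vapply(-pmax_v, edf_num, "", width = 8L),
              rep(edf_num(-1, 8L), ns - nch)), collapse = ""))  # phys min
  wr(paste0(c(vapply(pmax_v, edf_num, "", width = 8L),
              rep(edf_num(1, 8L), ns - nch)), collapse = ""))   # phys max
  wr(strrep(edf_pad(-32768, 8L), ns))                # dig min
  wr(strrep(edf_pad(32767, 8L), ns))                 # dig max
  wr(strrep(" ", 80L * ns))                          # prefiltering
  spr <- c(rep(fs, nch), if (edfplus_annotations) tal_bytes %/% 2L)
  wr(paste0(vapply(spr, edf_pad, "", width = 8L), collapse = ""))
  wr(strrep(" ", 32L * ns))                          # reserved
  # data records
  padded <- cbind(rec$data, matrix(0, nch, n_rec * fs - n))
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(nch)) {
      dig <- round((padded[ch, cols] + pmax_v[ch]) / (2 * pmax_v[ch]) * 65535 - 32768)
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
    if (edfplus_annotations) {
      tb <- charToRaw(tal_chunks[r])
      tb[tb == as.raw(1L)] <- as.raw(0L)  # 0x01 placeholder -> TAL NUL
      writeBin(c(tb, raw(tal_bytes - length(tb))), con)
    }
  }
  if (sidecar) {
    utils::write.csv(rec$annotations, sidecar_path(path), row.names = FALSE)
  }
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), "_events.csv")
}

read_edf_header <- function(con) {
  rd <- function(width) rawToChar(readBin(con, "raw", width))
  num <- function(width) suppressWarnings(as.numeric(trimws(rd(width))))
  h <- list()
  h$version <- trimws(rd(8L))
  h$patient <- trimws(rd(80L))
  h$recording <- trimws(rd(80L))
  h$startdate <- trimws(rd(8L)); h$starttime <- trimws(rd(8L))
  h$header_bytes <- num(8L)
  h$reserved <- trimws(rd(44L))
  h$n_records <- num(8L)
  h$record_dur <- num(8L)
  h$ns <- as.integer(num(4L))
  if (is.na(h$ns) || h$ns < 1L) stop("EDF header: bad signal count",
                                     call. = FALSE)
  fld <- function(width, f = trimws) {
    vapply(seq_len(h$ns), function(i) f(rd(width)), "")
  }
  h$labels <- fld(16L)
  h$transducer <- fld(80L)
  h$phys_dim <- fld(8L)
  h$phys_min <- as.numeric(fld(8L))
  h$phys_max <- as.numeric(fld(8L))
  h$dig_min <- as.numeric(fld(8L))
  h$dig_max <- as.numeric(fld(8L))
  h$prefilter <- fld(80L)
  h$spr <- as.integer(as.numeric(fld(8L)))
  h$sig_reserved <- fld(32L)
  if (anyNA(c(h$header_bytes, h$n_records, h$record_dur, h$phys_min,
              h$phys_max, h$dig_min, h$dig_max, h$spr))) {
    stop("unreadable EDF header field", call. = FALSE)
  }
  h
}

# parse EDF+ time-stamped annotation lists (TALs) from raw
# annotation-signal bytes; TALs are NUL-separated, fields 0x14-separated,
# onset and duration 0x15-separated
parse_tals <- function(bytes) {
  tal_raw <- split(bytes, cumsum(bytes == as.raw(0L)))
  starts <- ends <- numeric(); labs <- character()
  for (tr in tal_raw) {
    tr <- tr[tr != as.raw(0L)]
    if (length(tr) == 0L) next
    tal <- rawToChar(tr)
    Encoding(tal) <- "latin1"
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    if (length(parts) == 0L || !grepl("\x15", parts[1])) next  # timestamp
    od <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    onset <- suppressWarnings(as.numeric(od[1]))
    dur <- suppressWarnings(as.numeric(od[2]))
    if (is.na(onset) || is.na(dur) || dur <= 0) next
    lab <- if (length(parts) >= 2L && nzchar(parts[2])) parts[2] else
      "seizure"
    starts <- c(starts, onset); ends <- c(ends, onset + dur)
    labs <- c(labs, lab)
  }
  if (length(starts) == 0L) event_list() else event_list(starts, ends, labs)
}

#' Read an EEG recording
#'
#' Reads an EDF/EDF+ file (`dialect = "edf"`) or the package's internal
#' serialized container (`dialect = "internal"`, an RDS of a [recording()]).
#' Channel labels are preserved verbatim; no renaming happens on read.
#' Annotations come from an EDF+ annotation channel when present, otherwise
#' from the sidecar CSV `<path minus extension>_events.csv`
#' (columns `start_s,end_s,label`) if it exists.
#'
#' @param path File path.
#' @param dialect `"edf"` (default) or `"internal"`.
#' @return A [recording()].
#' @export
read_recording <- function(path, dialect = c("edf", "internal")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "internal") {
    rec <- readRDS(path)
    if (!inherits(rec, "recording")) {
      stop("internal container does not hold a recording", call. = FALSE)
    }
    return(rec)
  }
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  h <- read_edf_header(con)
  is_annot <- h$labels == "EDF Annotations"
  sig_idx <- which(!is_annot)
  if (length(sig_idx) == 0L) stop("EDF file has zero data channels",
                                  call. = FALSE)
  if (h$record_dur <= 0) stop("EDF header: non-positive record duration",
                              call. = FALSE)
  n_rec <- as.integer(h$n_records)
  data <- matrix(0, length(sig_idx), n_rec * h$spr[sig_idx[1]])
  if (length(unique(h$spr[sig_idx])) != 1L) {
    stop("EDF signals with heterogeneous sampling rates are not supported",
         call. = FALSE)
  }
  ann_bytes <- raw()
  for (r in seq_len(n_rec)) {
    for (s in seq_len(h$ns)) {
      if (is_annot[s]) {
        ann_bytes <- c(ann_bytes, readBin(con, "raw", 2L * h$spr[s]))
      } else {
        dig <- readBin(con, "integer", h$spr[s], size = 2L, signed = TRUE,
                       endian = "little")
        gain <- (h$phys_max[s] - h$phys_min[s]) / (h$dig_max[s] - h$dig_min[s])
        row <- match(s, sig_idx)
        cols <- ((r - 1L) * h$spr[s] + 1L):(r * h$spr[s])
        data[row, cols] <- (dig - h$dig_min[s]) * gain + h$phys_min[s]
      }
    }
  }
  fs <- h$spr[sig_idx[1]] / h$record_dur
  events <- if (length(ann_bytes) > 0L) parse_tals(ann_bytes) else event_list()
  if (nrow(events) == 0L && file.exists(sidecar_path(path))) {
    sc <- utils::read.csv(sidecar_path(path), stringsAsFactors = FALSE)
    events <- as_event_list(sc)
  }
  recording(data, fs, channel_labels = h$labels[sig_idx],
            annotations = events,
            record_id = if (nzchar(h$patient)) h$patient else
              tools::file_path_sans_ext(basename(path)))
}

#' Write a recording
#'
#' Dispatches on dialect: `"edf"` calls [write_recording_edf()];
#' `"internal"` serializes the [recording()] object as RDS.
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @param dialect `"edf"` (default) or `"internal"`.
#' @param ... Passed to [write_recording_edf()] for the EDF dialect.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, dialect = c("edf", "internal"), ...) {
  dialect <- match.arg(dialect)
  if (dialect == "internal") {
    saveRDS(rec, path)
    return(invisible(path))
  }
  write_recording_edf(rec, path, ...)
}
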