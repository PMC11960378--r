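#' Construct a multichannel EEG recording
#'
#' The `recording` object is the carrier passed between pipeline stages:
#' a channels x samples signal matrix in microvolts, its sampling rate,
#' ordered channel labels, and a seizure annotation list in seconds.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param fs Sampling rate in Hz (> 0).
#' @param channel_labels Character vector, one label per row of `data`.
#' @param annotations An event list (see [event_list()]); events must lie
#'   within `[0, samples/fs]`.
#' @param record_id Identifier string.
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, channel_labels = rownames(data),
                      annotations = event_list(), record_id = "record") {
  stopifnot(is.matrix(data), is.numeric(data))
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  if (nrow(data) != length(channel_labels)) {
    stop("data row count must equal length(channel_labels)", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("all samples must be finite", call. = FALSE)
  }
  annotations <- as_event_list(annotations)
  dur <- ncol(data) / fs
  if (nrow(annotations) > 0L && any(annotations$end_s > dur + 1e-9)) {
    stop("annotations must lie within [0, samples/fs]", call. = FALSE)
  }
  rownames(data) <- channel_labels
  structure(
    list(data = data, fs = fs, channel_labels = as.character(channel_labels),
         annotations = annotations, record_id = as.character(record_id)),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording '%s': %d channels x %d samples @ %g Hz (%.1f s), %d annotated event(s)>\n",
              x$record_id, nrow(x$data), ncol(x$data), x$fs,
              ncol(x$data) / x$fs, nrow(x$annotations)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec A [recording()].
#' @return Scalar duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs

#' Tidy a recording into long format
#'
#' @param x A [recording()].
#' @param channels Optional character vector restricting channels.
#' @param ... Unused.
#' @return A tibble with columns `time_s`, `channel`, `uv`.
#' @export
tidy.recording <- function(x, channels = NULL, ...) {
  labs <- if (is.null(channels)) x$channel_labels else channels
  idx <- match(labs, x$channel_labels)
  if (anyNA(idx)) stop("unknown channel(s): ",
                       paste(labs[is.na(idx)], collapse = ", "), call. = FALSE)
  t <- (seq_len(ncol(x$data)) - 1L) / x$fs
  tibble::tibble(
    time_s = rep(t, times = length(idx)),
    channel = factor(rep(labs, each = ncol(x$data)), levels = labs),
    uv = as.vector(t(x$data[idx, , drop = FALSE]))
  )
}

#' Stacked-trace plot of a recording
#'
#' @param object A [recording()].
#' @param channels Channels to draw (default all).
#' @param t_lim Optional numeric length-2 time window in seconds.
#' @param spacing Vertical offset between traces in microvolts.
#' @param ... Unused.
#' @return A ggplot object; annotated events are shaded.
#' @export
autoplot.recording <- function(object, channels = NULL, t_lim = NULL,
                               spacing = 150, ...) {
  df <- tidy.recording(object, channels = channels)
  if (!is.null(t_lim)) {
    df <- dplyr::filter(df, .data$time_s >= t_lim[1], .data$time_s <= t_lim[2])
  }
  offs <- (nlevels(df$channel) - as.integer(df$channel)) * spacing
  df$y <- df$uv + offs
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$y,
                                        group = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::scale_y_continuous(
      breaks = (nlevels(df$channel) - seq_len(nlevels(df$channel))) * spacing,
      labels = levels(df$channel)) +
    ggplot2::labs(x = "time (s)", y = NULL, title = object$record_id)
  ev <- object$annotations
  if (!is.null(t_lim) && nrow(ev) > 0L) {
    ev <- dplyr::filter(ev, .data$end_s >= t_lim[1], .data$start_s <= t_lim[2])
  }
  if (nrow(ev) > 0L) {
    p <- p + ggplot2::annotate("rect", xmin = ev$start_s, xmax = ev$end_s,
                               ymin = -Inf, ymax = Inf, alpha = 0.15,
                               fill = "red")
  }
  p
}
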