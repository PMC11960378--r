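#' Decode per-frame probabilities into predicted events
#'
#' Frames with probability at or above `threshold` are grouped into
#' maximal runs; a run's interval spans from the first frame's window
#' start to the last frame's window end. Intervals separated by less than
#' `merge_gap_s` are merged, then intervals shorter than `min_dur_s` are
#' dropped.
#'
#' @param frame_probs Numeric vector of per-frame probabilities.
#' @param frame_times Matrix (frames x 2) of window start/end seconds,
#'   monotone in the start column.
#' @param threshold Decision threshold (default 0.5).
#' @param merge_gap_s Merge events closer than this (default 1 s).
#' @param min_dur_s Drop events shorter than this (default 1 s).
#' @return An [event_list()] tibble.
#' @export
probs_to_events <- function(frame_probs, frame_times, threshold = 0.5,
                            merge_gap_s = 1.0, min_dur_s = 1.0) {
  stopifnot(length(frame_probs) == nrow(frame_times))
  if (is.unsorted(frame_times[, 1])) {
    stop("frame_times must be monotone", call. = FALSE)
  }
  hot <- frame_probs >= threshold
  if (!any(hot)) return(event_list())
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  ivs <- cbind(frame_times[starts[runs], 1], frame_times[ends[runs], 2])
  # merge runs closer than merge_gap_s
  keep_s <- ivs[1, 1]; keep_e <- ivs[1, 2]
  out_s <- out_e <- numeric()
  for (i in seq_len(nrow(ivs))[-1L]) {
    if (ivs[i, 1] - keep_e < merge_gap_s) {
      keep_e <- max(keep_e, ivs[i, 2])
    } else {
      out_s <- c(out_s, keep_s); out_e <- c(out_e, keep_e)
      keep_s <- ivs[i, 1]; keep_e <- ivs[i, 2]
    }
  }
  out_s <- c(out_s, keep_s); out_e <- c(out_e, keep_e)
  long <- (out_e - out_s) >= min_dur_s
  if (!any(long)) return(event_list())
  event_list(out_s[long], out_e[long], "detected")
}

#' Match predicted events to ground truth by temporal overlap
#'
#' Greedy one-to-one matching in time order: a true event is a true
#' positive when some not-yet-matched predicted event overlaps it by more
#' than `min_overlap_s` (default 2 s); unmatched true events are false
#' negatives; predicted events that overlap no true event by more than
#' the threshold are false positives.
#'
#' @param predicted Predicted [event_list()].
#' @param truth Ground-truth [event_list()].
#' @param min_overlap_s Required overlap in seconds (strictly greater
#'   than).
#' @return List with `tp`, `fp`, `fn` counts and `matched_pairs` (tibble:
#'   true/predicted interval bounds and overlap seconds).
#' @export
match_events <- function(predicted, truth, min_overlap_s = 2.0) {
  predicted <- as_event_list(predicted)
  truth <- as_event_list(truth)
  used <- rep(FALSE, nrow(predicted))
  pairs <- tibble::tibble(true_start = numeric(), true_end = numeric(),
                          pred_start = numeric(), pred_end = numeric(),
                          overlap_s = numeric())
  tp <- 0L
  for (i in seq_len(nrow(truth))) {
    if (nrow(predicted) == 0L) break
    ov <- interval_overlap(truth$start_s[i], truth$end_s[i], predicted)
    ov[used] <- 0
    j <- which(ov > min_overlap_s)
    if (length(j) > 0L) {
      j <- j[1L]                       # earliest candidate in time order
      used[j] <- TRUE
      tp <- tp + 1L
      pairs <- dplyr::bind_rows(pairs, tibble::tibble(
        true_start = truth$start_s[i], true_end = truth$end_s[i],
        pred_start = predicted$start_s[j], pred_end = predicted$end_s[j],
        overlap_s = ov[j]))
    }
  }
  fn <- nrow(truth) - tp
  # a predicted event is FP unless it overlaps some truth by > threshold
  fp <- 0L
  for (j in seq_len(nrow(predicted))) {
    ov <- interval_overlap(predicted$start_s[j], predicted$end_s[j], truth)
    if (length(ov) == 0L || max(ov) <= min_overlap_s) fp <- fp + 1L
  }
  list(tp = tp, fp = fp, fn = fn, matched_pairs = pairs)
}

#' Count true-negative background windows
#'
#' Events carry no natural negative count, so background time (the
#' complement of the true events) is tiled into non-overlapping windows of
#' `tn_window_s` seconds; a window counts as a true negative when no
#' predicted event intersects it.
#'
#' @param truth Ground-truth [event_list()].
#' @param predicted Predicted [event_list()].
#' @param record_dur_s Record duration in seconds.
#' @param tn_window_s Window length (default 10 s).
#' @return Integer TN count.
#' @export
count_true_negatives <- function(truth, predicted, record_dur_s,
                                 tn_window_s = 10) {
  stopifnot(record_dur_s >= 0)
  truth <- as_event_list(truth)
  predicted <- as_event_list(predicted)
  # background segments = complement of truth in [0, record_dur_s]
  bg_start <- 0
  segs <- list()
  for (i in seq_len(nrow(truth))) {
    if (truth$start_s[i] > bg_start) {
      segs[[length(segs) + 1L]] <- c(bg_start, truth$start_s[i])
    }
    bg_start <- max(bg_start, truth$end_s[i])
  }
  if (bg_start < record_dur_s) {
    segs[[length(segs) + 1L]] <- c(bg_start, record_dur_s)
  }
  tn <- 0L
  for (seg in segs) {
    n_win <- floor((seg[2] - seg[1]) / tn_window_s)
    for (w in seq_len(n_win)) {
      w0 <- seg[1] + (w - 1) * tn_window_s
      w1 <- w0 + tn_window_s
      ov <- interval_overlap(w0, w1, predicted)
      if (length(ov) == 0L || max(ov) <= 0) tn <- tn + 1L
    }
  }
  tn
}

#' Compute the five detection metrics from confusion counts
#'
#' `TPR = TP/(TP+FN)`, `TNR = TN/(TN+FP)`, `PPV = TP/(TP+FP)`,
#' `NPV = TN/(TN+FN)`, and `F1 = 2*TPR*PPV/(TPR+PPV)` (the harmonic mean
#' of sensitivity and positive predictive value). Zero denominators yield
#' `NA` (flagged undefined), never a division error.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @param matched_pairs Optional tibble from [match_events()].
#' @param config_echo Optional named list of thresholds used upstream.
#' @return An object of class `eval_report`.
#' @export
compute_metrics <- function(tp, fp, tn, fn, matched_pairs = NULL,
                            config_echo = NULL) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  tpr <- safe_div(tp, tp + fn)
  tnr <- safe_div(tn, tn + fp)
  ppv <- safe_div(tp, tp + fp)
  npv <- safe_div(tn, tn + fn)
  f1 <- if (!is.na(tpr) && !is.na(ppv) && (tpr + ppv) > 0) {
    2 * tpr * ppv / (tpr + ppv)
  } else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, tpr = tpr, tnr = tnr,
                 ppv = ppv, npv = npv, f1 = f1,
                 matched_pairs = matched_pairs,
                 config_echo = config_echo),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report: TP %d FP %d TN %d FN %d | TPR %.3f TNR %.3f PPV %.3f NPV %.3f F1 %.3f>\n",
    x$tp, x$fp, x$tn, x$fn, x$tpr, x$tnr, x$ppv, x$npv, x$f1))
  invisible(x)
}

#' Tidy an evaluation report into one row per metric
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble with `metric`, `value`, `defined`.
#' @export
tidy.eval_report <- function(x, ...) {
  v <- c(tpr = x$tpr, tnr = x$tnr, ppv = x$ppv, npv = x$npv, f1 = x$f1)
  tibble::tibble(metric = names(v), value = unname(v),
                 defined = !is.na(unname(v)))
}

#' One-row summary of an evaluation report
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row tibble with counts and metrics.
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn, tpr = x$tpr,
                 tnr = x$tnr, ppv = x$ppv, npv = x$npv, f1 = x$f1)
}

#' Serialize an evaluation report to JSON
#' @param x An `eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(x, path) {
  jsonlite::write_json(
    list(counts = list(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn),
         metrics = list(tpr = x$tpr, tnr = x$tnr, ppv = x$ppv,
                        npv = x$npv, f1 = x$f1),
         config_echo = x$config_echo),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Event-level evaluation of predictions against truth
#'
#' Convenience wrapper: [match_events()] + [count_true_negatives()] +
#' [compute_metrics()].
#'
#' @param predicted Predicted [event_list()].
#' @param truth Ground-truth [event_list()].
#' @param record_dur_s Record duration in seconds.
#' @param min_overlap_s Overlap rule threshold (default 2 s).
#' @param tn_window_s Background tiling window (default 10 s).
#' @return An `eval_report`.
#' @export
evaluate_events <- function(predicted, truth, record_dur_s,
                            min_overlap_s = 2.0, tn_window_s = 10) {
  m <- match_events(predicted, truth, min_overlap_s)
  tn <- count_true_negatives(truth, predicted, record_dur_s, tn_window_s)
  compute_metrics(m$tp, m$fp, tn, m$fn, matched_pairs = m$matched_pairs,
                  config_echo = list(min_overlap_s = min_overlap_s,
                                     tn_window_s = tn_window_s))
}

#' Metric bar chart for an evaluation report
#' @param object An `eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidy.eval_report(object)
  ggplot2::ggplot(df[df$defined, ],
                  ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_col() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL)
}
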