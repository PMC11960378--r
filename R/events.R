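#' Construct a normalized seizure event list
#'
#' An event list is the common carrier for ground-truth seizure annotations
#' and for detector output: an ordered set of half-open intervals
#' `[start_s, end_s)` in seconds from record start, with a free-text label.
#' Construction normalizes the intervals: events are sorted by onset and
#' overlapping or touching events that share a label are merged, so any
#' permutation of the same intervals yields an identical list.
#'
#' @param start_s Numeric vector of onsets in seconds (>= 0).
#' @param end_s Numeric vector of offsets in seconds; must satisfy
#'   `end_s > start_s` elementwise.
#' @param label Character vector of event labels, recycled; default
#'   `"seizure"`.
#' @return A tibble with columns `start_s`, `end_s`, `label`, sorted by
#'   `start_s`, with same-label overlapping/touching intervals merged.
#' @examples
#' event_list(c(30, 10, 12), c(40, 13, 20))
#' @export
event_list <- function(start_s = numeric(), end_s = numeric(),
                       label = "seizure") {
  if (length(start_s) != length(end_s)) {
    stop("start_s and end_s must have the same length", call. = FALSE)
  }
  if (length(start_s) == 0L) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric(),
                          label = character()))
  }
  if (any(!is.finite(start_s)) || any(!is.finite(end_s))) {
    stop("event times must be finite", call. = FALSE)
  }
  if (any(start_s < 0)) stop("event onsets must be >= 0", call. = FALSE)
  if (any(end_s <= start_s)) {
    stop("every event must satisfy end_s > start_s", call. = FALSE)
  }
  ev <- tibble::tibble(start_s = as.numeric(start_s),
                       end_s = as.numeric(end_s),
                       label = rep_len(as.character(label), length(start_s)))
  ev <- dplyr::arrange(ev, .data$start_s, .data$end_s)
  # merge overlapping or touching intervals within each label
  merged <- ev |>
    dplyr::group_by(.data$label) |>
    dplyr::group_modify(function(df, key) {
      out_start <- df$start_s[1L]
      out_end <- df$end_s[1L]
      starts <- ends <- numeric()
      for (i in seq_len(nrow(df))[-1L]) {
        if (df$start_s[i] <= out_end) {
          out_end <- max(out_end, df$end_s[i])
        } else {
          starts <- c(starts, out_start); ends <- c(ends, out_end)
          out_start <- df$start_s[i]; out_end <- df$end_s[i]
        }
      }
      tibble::tibble(start_s = c(starts, out_start), end_s = c(ends, out_end))
    }) |>
    dplyr::ungroup() |>
    dplyr::select("start_s", "end_s", "label") |>
    dplyr::arrange(.data$start_s, .data$end_s)
  merged
}

#' Validate a data frame as an event list
#' @param events A data frame with `start_s`, `end_s` (and optionally
#'   `label`) columns.
#' @return A normalized event-list tibble (see [event_list()]).
#' @export
as_event_list <- function(events) {
  if (is.null(events)) return(event_list())
  stopifnot(is.data.frame(events))
  if (nrow(events) == 0L) return(event_list())
  lab <- if ("label" %in% names(events)) events$label else "seizure"
  event_list(events$start_s, events$end_s, lab)
}

#' Total event duration in seconds
#' @param events An event-list tibble.
#' @return Scalar total duration.
#' @export
event_seconds <- function(events) {
  if (nrow(events) == 0L) return(0)
  sum(events$end_s - events$start_s)
}

# overlap in seconds between one interval and each row of an event list
interval_overlap <- function(start_s, end_s, events) {
  if (nrow(events) == 0L) return(numeric())
  pmax(0, pmin(end_s, events$end_s) - pmax(start_s, events$start_s))
}
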