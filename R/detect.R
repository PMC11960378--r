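#' Preprocess a recording into normalized feature examples
#'
#' The standard front end of the detector: canonical 19-channel selection,
#' anti-aliased resampling to the working rate, order-12 Butterworth
#' band-pass, combined spectrogram + raw features cut into 64-frame
#' examples, and per-record normalization.
#'
#' @param rec A [recording()] (any channel superset of the canonical 19).
#' @param filter A [filter_spec()].
#' @param stft An [stft_spec()].
#' @param target_fs Working sampling rate in Hz (default 100).
#' @param events Ground-truth events used for frame labels; defaults to
#'   the recording's annotations (labels are ignored at detection time).
#' @return List of normalized feature examples.
#' @export
preprocess_recording <- function(rec, filter = filter_spec(),
                                 stft = stft_spec(), target_fs = 100,
                                 events = rec$annotations) {
  canon <- all(rec$channel_labels == CANONICAL_CHANNELS)
  if (!canon) rec <- select_channels(rec)
  if (abs(rec$fs - target_fs) > 1e-9) {
    rec <- resample_recording(rec, target_fs)
  }
  rec <- bandpass_filter(rec, filter)
  examples <- make_examples(rec, events = events, spec = stft)
  normalize_examples(examples, stft)
}

#' Detect absence-seizure events in a recording
#'
#' Runs the full inference pipeline: [preprocess_recording()], per-frame
#' probabilities from the model, and [probs_to_events()] decoding. Frame
#' probabilities from consecutive examples of the record are concatenated
#' (padded frames dropped) before decoding.
#'
#' @param model A trained `swd_model` (or `swd_fit`).
#' @param rec A [recording()].
#' @param threshold,merge_gap_s,min_dur_s Decoding parameters, see
#'   [probs_to_events()].
#' @param filter,stft,target_fs Preprocessing parameters.
#' @return List with `events` (predicted [event_list()]) and `frames`
#'   (tibble: frame start/end seconds and probability).
#' @export
detect_seizures <- function(model, rec, threshold = 0.5, merge_gap_s = 1.0,
                            min_dur_s = 1.0, filter = filter_spec(),
                            stft = stft_spec(), target_fs = 100) {
  if (inherits(model, "swd_fit")) model <- model$model
  examples <- preprocess_recording(rec, filter, stft, target_fs)
  if (length(examples) == 0L) {
    return(list(events = event_list(),
                frames = tibble::tibble(start_s = numeric(),
                                        end_s = numeric(),
                                        prob = numeric())))
  }
  probs <- predict(model, examples)
  live <- lapply(seq_along(examples), function(i) {
    sel <- examples[[i]]$mask > 0
    cbind(examples[[i]]$frame_times[sel, , drop = FALSE],
          probs[i, sel])
  })
  flat <- do.call(rbind, live)
  frames <- tibble::tibble(start_s = flat[, 1], end_s = flat[, 2],
                           prob = flat[, 3])
  events <- probs_to_events(frames$prob, as.matrix(frames[, 1:2]),
                            threshold = threshold,
                            merge_gap_s = merge_gap_s,
                            min_dur_s = min_dur_s)
  list(events = events, frames = frames)
}
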