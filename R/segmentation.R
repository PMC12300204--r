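#' Filter stimulus positions contaminated by missing samples
#'
#' A stimulus position is kept only if its full dwell block (nominally 1000
#' samples) contains no `NaN` horizontal gaze. Blink-contaminated positions
#' are discarded wholesale rather than interpolated: the dynamics inside the
#' window are the biometric signal and must be genuine.
#'
#' @param rec A [gaze_recording()].
#' @param schedule The [stimulus_schedule()] the recording was acquired under.
#' @return Integer vector of valid position indices (possibly empty).
#' @export
filter_valid_positions <- function(rec, schedule) {
  stopifnot(inherits(rec, "gaze_recording"),
            inherits(schedule, "stimulus_schedule"))
  n_needed <- schedule$count * schedule$dwell_ms
  if (length(rec) < n_needed) {
    stop_gazeid(sprintf("recording (%d samples) does not cover the schedule (%d needed)",
                        length(rec), n_needed),
                "gazeid_validation_error")
  }
  ok <- vapply(seq_len(schedule$count), function(p) {
    idx <- ((p - 1L) * schedule$dwell_ms + 1L):(p * schedule$dwell_ms)
    !anyNA(rec$gaze_x[idx])
  }, logical(1))
  which(ok)
}

#' Select stimulus positions common to all trials
#'
#' Takes the intersection of the per-trial valid-position sets and returns the
#' first `x_count` of them in stimulus order, so every subject and session
#' contributes windows from the same stimulus jumps.
#'
#' @param per_trial_valid List of integer vectors as returned by
#'   [filter_valid_positions()], one per trial.
#' @param x_count Number of positions to retain (the experiments use 50 of
#'   the 100 presented).
#' @return Integer vector of length `x_count`.
#' @export
select_common_positions <- function(per_trial_valid, x_count) {
  if (x_count < 1L) {
    stop_gazeid("x_count must be >= 1", "gazeid_validation_error")
  }
  common <- sort(Reduce(intersect, per_trial_valid))
  if (length(common) < x_count) {
    stop_gazeid(sprintf(paste0("insufficient clean positions: requested %d but only ",
                               "%d are valid across all trials"),
                        x_count, length(common)),
                "gazeid_insufficient_data")
  }
  common[seq_len(x_count)]
}

#' Extract the event window of one stimulus position
#'
#' The 303 horizontal-position samples immediately following stimulus onset.
#' The window covers the three oculomotor events elicited by the jump --
#' saccadic latency, the saccade itself, and the start of fixation -- and its
#' length is chosen so that three successive point-to-point derivatives leave
#' exactly 300 samples (3 segments of 100).
#'
#' @param rec A [gaze_recording()].
#' @param position_index Stimulus position (1-based).
#' @param schedule The [stimulus_schedule()].
#' @param window_len Window length in samples (default 303).
#' @return An object of class `position_window` with field `raw_x`.
#' @export
extract_window <- function(rec, position_index, schedule, window_len = 303) {
  stopifnot(inherits(rec, "gaze_recording"),
            inherits(schedule, "stimulus_schedule"))
  if (position_index < 1L || position_index > schedule$count) {
    stop_gazeid(sprintf("position_index %d out of range 1..%d",
                        position_index, schedule$count),
                "gazeid_validation_error")
  }
  onset <- (position_index - 1L) * schedule$dwell_ms + 1L
  if (onset + window_len - 1L > length(rec)) {
    stop_gazeid("window extends past the end of the recording",
                "gazeid_validation_error")
  }
  raw_x <- rec$gaze_x[onset:(onset + window_len - 1L)]
  if (anyNA(raw_x)) {
    stop_gazeid(sprintf("NaN inside the window of position %d", position_index),
                "gazeid_validation_error")
  }
  structure(list(subject_id = rec$subject_id, session_id = rec$session_id,
                 position_index = position_index, raw_x = raw_x),
            class = "position_window")
}

#' Split a window's derivative support into segments
#'
#' The 303-sample window supports a 300-sample third-derivative series; that
#' common support is split into `g` contiguous, non-overlapping segments of
#' `segment_len` samples each (default 3 x 100).
#'
#' @param window A [extract_window()] result.
#' @param g Number of segments.
#' @param segment_len Samples per segment.
#' @return An object of class `segment_bundle`: list of `g` index ranges over
#'   the common derivative support, plus window provenance.
#' @export
split_segments <- function(window, g = 3, segment_len = 100) {
  stopifnot(inherits(window, "position_window"))
  support <- length(window$raw_x) - 3L
  if (g * segment_len != support) {
    stop_gazeid(sprintf("window supports %d derivative samples; cannot split into %d x %d",
                        support, g, segment_len),
                "gazeid_validation_error")
  }
  segments <- lapply(seq_len(g), function(s) {
    ((s - 1L) * segment_len + 1L):(s * segment_len)
  })
  structure(list(window = window, segments = segments, g = g,
                 segment_len = segment_len),
            class = "segment_bundle")
}
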