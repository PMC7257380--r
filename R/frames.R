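frame_starts <- function(span_start, span_end, frame_s, step_s) {
  if (span_end - span_start < frame_s) return(numeric(0))
  seq(span_start, span_end - frame_s, by = step_s)
}

#' Cut a recording into fixed-length labeled frames
#'
#' Inside each retained seizure interval frames advance by `seizure_step_s`
#' (overlapping frames compensate for the scarcity of ictal data); everywhere
#' else they advance by `nonseizure_step_s`. Each frame is labeled with
#' [assign_state()]; frames that straddle a state boundary or fall in no state
#' region are dropped.
#'
#' @param recording An [eeg_recording()] (denoise first with
#'   [denoise_recording()] if desired).
#' @param windows A [label_windows()].
#' @param frame_s Frame length in seconds (default 4); `frame_s *
#'   sampling_rate` must be an integer.
#' @param seizure_step_s Step between frame starts inside seizures (default 2).
#' @param nonseizure_step_s Step outside seizures (default 4).
#' @param source_id Identifier stored in each frame.
#' @return List of [labeled_frame()] objects (possibly empty).
#' @export
segment_frames <- function(recording, windows = label_windows(), frame_s = 4,
                           seizure_step_s = 2, nonseizure_step_s = 4,
                           source_id = "recording") {
  stopifnot(inherits(recording, "eeg_recording"),
            seizure_step_s > 0, nonseizure_step_s > 0)
  fs <- recording$sampling_rate
  flen <- frame_s * fs
  if (abs(flen - round(flen)) > 1e-9)
    stopf("frame_s * sampling_rate must be an integer")
  flen <- as.integer(round(flen))
  dur <- recording_duration(recording)
  iv <- recording$seizure_intervals
  kept <- iv[iv[, 2] - iv[, 1] >= windows$min_seizure_s, , drop = FALSE]

  starts <- numeric(0)
  steps_from <- 0
  for (k in seq_len(nrow(kept))) {
    starts <- c(starts, frame_starts(steps_from, kept[k, 1], frame_s,
                                     nonseizure_step_s),
                frame_starts(kept[k, 1], kept[k, 2], frame_s, seizure_step_s))
    steps_from <- kept[k, 2]
  }
  starts <- c(starts, frame_starts(steps_from, dur, frame_s, nonseizure_step_s))

  out <- list()
  for (t0 in starts) {
    lab <- assign_state(t0, t0 + frame_s, recording, windows)
    if (is.na(lab)) next
    i0 <- round(t0 * fs)
    out[[length(out) + 1L]] <- labeled_frame(
      recording$samples[, (i0 + 1):(i0 + flen), drop = FALSE],
      lab, t_start_s = t0, source_id = source_id, sampling_rate = fs)
  }
  out
}

#' Labels of a list of frames
#' @param frames List of [labeled_frame()] objects.
#' @return Factor with levels [state_labels()].
#' @export
frame_labels <- function(frames) {
  factor(vapply(frames, function(f) f$label, ""), levels = state_labels())
}
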