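#' Multichannel EEG recording
#'
#' Container for a channels-by-samples signal matrix (microvolts) with its
#' sampling rate, channel names and annotated seizure intervals.
#'
#' @param samples Numeric matrix, `n_channels x n_samples`.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_names Character vector (defaults to `EEG 01`, ...).
#' @param seizure_intervals Matrix / data frame of (onset_s, offset_s) rows.
#' @return Object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate, channel_names = NULL,
                          seizure_intervals = NULL) {
  samples <- as.matrix(samples)
  stopifnot(nrow(samples) >= 1, sampling_rate > 0)
  channel_names <- channel_names %||% sprintf("EEG %02d", seq_len(nrow(samples)))
  stopifnot(length(channel_names) == nrow(samples))
  iv <- normalize_intervals(seizure_intervals)
  dur <- ncol(samples) / sampling_rate
  if (nrow(iv) && (any(iv < 0) || any(iv[, 2] > dur + 1e-9)))
    stopf("seizure intervals must lie within [0, %g] s", dur)
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 channel_names = channel_names, seizure_intervals = iv),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d seizure(s)\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              ncol(x$samples) / x$sampling_rate, nrow(x$seizure_intervals)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording An [eeg_recording()].
#' @return Numeric scalar.
#' @export
recording_duration <- function(recording) {
  ncol(recording$samples) / recording$sampling_rate
}

#' Fixed-length labeled EEG segment
#'
#' @param samples Numeric matrix, `n_channels x frame_len`.
#' @param label One of [state_labels()].
#' @param t_start_s Start time of the frame within its source recording.
#' @param source_id Identifier of the source recording.
#' @param sampling_rate Sampling rate in Hz.
#' @return Object of class `labeled_frame`.
#' @export
labeled_frame <- function(samples, label, t_start_s = 0, source_id = "",
                          sampling_rate = 256) {
  check_state(label)
  samples <- as.matrix(samples)
  structure(list(samples = samples, label = label, t_start_s = t_start_s,
                 source_id = source_id, sampling_rate = sampling_rate),
            class = "labeled_frame")
}

#' @export
print.labeled_frame <- function(x, ...) {
  cat(sprintf("<labeled_frame> %s: %d x %d @ %g Hz (t0 = %g s, %s)\n",
              x$label, nrow(x$samples), ncol(x$samples), x$sampling_rate,
              x$t_start_s, x$source_id))
  invisible(x)
}
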