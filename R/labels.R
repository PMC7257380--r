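#' Labeling windows for epileptic state assignment
#'
#' Defines the time geometry of the four states relative to annotated seizure
#' intervals: preictal II is the final `preictal_II_min` minutes before onset,
#' preictal I the annulus from `preictal_I_min` to `preictal_II_min` minutes
#' before onset, and interictal requires at least `interictal_gap_min` minutes
#' of separation from every seizure. Seizures shorter than `min_seizure_s`
#' seconds are dropped before labeling (but still block interictal labels in
#' their neighborhood).
#'
#' @param preictal_II_min Minutes before onset for preictal II (default 10).
#' @param preictal_I_min Minutes before onset for preictal I (default 30).
#' @param interictal_gap_min Minimum distance in minutes from any seizure for
#'   a window to count as interictal (default 60).
#' @param min_seizure_s Minimum seizure duration in seconds to keep (default
#'   10, the upper end of the 6-10 s persistence rule used when screening
#'   scalp-EEG abnormalities).
#' @return Object of class `label_windows`.
#' @export
label_windows <- function(preictal_II_min = 10, preictal_I_min = 30,
                          interictal_gap_min = 60, min_seizure_s = 10) {
  if (!(0 < preictal_II_min && preictal_II_min < preictal_I_min &&
        preictal_I_min < interictal_gap_min))
    stopf("need 0 < preictal_II_min < preictal_I_min < interictal_gap_min")
  if (min_seizure_s <= 0) stopf("min_seizure_s must be > 0")
  structure(list(preictal_II_s = preictal_II_min * 60,
                 preictal_I_s = preictal_I_min * 60,
                 interictal_gap_s = interictal_gap_min * 60,
                 min_seizure_s = min_seizure_s),
            class = "label_windows")
}

#' Assign an epileptic state label to a time window
#'
#' A window gets a label only when it lies entirely inside one state region:
#' `seizure` inside a (retained) seizure interval; `preictal_II` inside the 10
#' minutes before an onset; `preictal_I` inside the 30-to-10-minute pre-onset
#' annulus; `interictal` when at least the configured gap away from every
#' seizure (including seizures dropped by the duration filter). Windows
#' straddling a region boundary, or falling in none of the regions, return
#' `NA` and should be discarded.
#'
#' @param t_start_s,t_end_s Window bounds in seconds, `0 <= t_start < t_end <=`
#'   recording duration.
#' @param recording An [eeg_recording()] (supplies seizure intervals and
#'   duration).
#' @param windows A [label_windows()].
#' @return A state label string, or `NA_character_` for discard.
#' @export
assign_state <- function(t_start_s, t_end_s, recording,
                         windows = label_windows()) {
  stopifnot(inherits(recording, "eeg_recording"))
  dur <- recording_duration(recording)
  if (!(t_start_s >= 0 && t_start_s < t_end_s && t_end_s <= dur + 1e-9))
    stopf("invalid window (%g, %g) for a %g s recording",
          t_start_s, t_end_s, dur)
  iv <- recording$seizure_intervals
  kept <- iv[iv[, 2] - iv[, 1] >= windows$min_seizure_s, , drop = FALSE]

  for (k in seq_len(nrow(kept))) {
    if (t_start_s >= kept[k, 1] && t_end_s <= kept[k, 2]) return("seizure")
  }
  for (k in seq_len(nrow(kept))) {
    on <- kept[k, 1]
    if (t_start_s >= on - windows$preictal_II_s && t_end_s <= on)
      return("preictal_II")
  }
  for (k in seq_len(nrow(kept))) {
    on <- kept[k, 1]
    if (t_start_s >= on - windows$preictal_I_s &&
        t_end_s <= on - windows$preictal_II_s)
      return("preictal_I")
  }
  # interictal: far from every annotated seizure, dropped ones included
  far <- TRUE
  for (k in seq_len(nrow(iv))) {
    if (!(t_start_s >= iv[k, 2] + windows$interictal_gap_s ||
          t_end_s <= iv[k, 1] - windows$interictal_gap_s)) {
      far <- FALSE
      break
    }
  }
  if (far) "interictal" else NA_character_
}
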