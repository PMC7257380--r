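# Shared fixtures. Small channel counts keep unit tests fast; tests that
# check the study conditions themselves (23 channels, 256 Hz) build their own
# full-size configs.

small_config <- function(seed = 7, n_channels = 4, ...) {
  synth_config(n_channels = n_channels, seed = seed, ...)
}

gen_frames <- function(config, n_per_class, duration_s = 4) {
  frames <- list()
  for (st in state_labels())
    for (i in seq_len(n_per_class))
      frames[[length(frames) + 1L]] <-
        generate_state_frame(st, config, duration_s, frame_index = i)
  frames
}

frames_to_images <- function(frames, size = 32) {
  imgs <- lapply(frames, function(f) render_image(build_psded(f), size))
  eegstates:::as_image_batch(imgs)
}

# independent relabeling oracle for assign_state: checks each rule directly
# from the interval list, in a different (per-rule scan) formulation
oracle_label <- function(t0, t1, intervals, min_seizure_s = 10,
                         pre2 = 600, pre1 = 1800, gap = 3600) {
  keep <- intervals[intervals[, 2] - intervals[, 1] >= min_seizure_s, ,
                    drop = FALSE]
  inside <- function(a, b) t0 >= a && t1 <= b
  if (nrow(keep) > 0) {
    for (r in seq_len(nrow(keep)))
      if (inside(keep[r, 1], keep[r, 2])) return("seizure")
    for (r in seq_len(nrow(keep)))
      if (inside(keep[r, 1] - pre2, keep[r, 1])) return("preictal_II")
    for (r in seq_len(nrow(keep)))
      if (inside(keep[r, 1] - pre1, keep[r, 1] - pre2)) return("preictal_I")
  }
  if (nrow(intervals) == 0) return("interictal")
  d <- vapply(seq_len(nrow(intervals)), function(r) {
    if (t1 <= intervals[r, 1]) intervals[r, 1] - t1
    else if (t0 >= intervals[r, 2]) t0 - intervals[r, 2]
    else -1
  }, 0)
  if (all(d >= gap)) "interictal" else NA_character_
}
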