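#' State spectral profile for the synthetic EEG generator
#'
#' Describes how signal power is distributed over frequency for one epileptic
#' state. A generated channel is a sum of band-limited Gaussian noise
#' components (one per row of `bands`, variance proportional to `weight`),
#' broadband Gaussian noise with relative power `noise_floor`, and optional
#' deterministic sinusoids (`tones`).
#'
#' @param state One of [state_labels()].
#' @param bands Data frame with columns `low_hz`, `high_hz`, `weight`
#'   (relative power, >= 0). Edges must satisfy 0 <= low < high <= Nyquist of
#'   the config the profile is used with.
#' @param noise_floor Relative broadband noise power (>= 0).
#' @param tones Optional data frame with columns `freq_hz`, `amplitude`:
#'   deterministic sinusoidal components added to every channel.
#' @return An object of class `state_profile`.
#' @export
spectral_profile <- function(state, bands, noise_floor = 0.05, tones = NULL) {
  check_state(state)
  bands <- as.data.frame(bands)
  stopifnot(all(c("low_hz", "high_hz", "weight") %in% names(bands)))
  if (any(bands$weight < 0) || noise_floor < 0)
    stopf("relative powers must be non-negative")
  if (any(bands$low_hz < 0) || any(bands$low_hz >= bands$high_hz))
    stopf("band edges must satisfy 0 <= low < high")
  has_tone <- !is.null(tones) && nrow(tones) > 0 && any(tones$amplitude > 0)
  if (!any(bands$weight > 0) && noise_floor == 0 && !has_tone)
    stopf("profile for '%s' has no component with positive power", state)
  structure(list(state = state, bands = bands, noise_floor = noise_floor,
                 tones = tones),
            class = "state_profile")
}

#' Default spectral profiles for the four epileptic states
#'
#' Seizure activity concentrates power at low frequencies (1-8 Hz) while the
#' interictal baseline is dominated by higher frequencies (16-64 Hz). The two
#' preictal states share the interictal shape but carry 10% (preictal I) and
#' 30% (preictal II) more low-band power, making them deliberately similar to
#' each other -- the hard pair for any downstream classifier.
#'
#' @return Named list of four [spectral_profile()] objects.
#' @export
default_profiles <- function() {
  base <- data.frame(low_hz  = c(1,    8,   16),
                     high_hz = c(8,   16,   64),
                     weight  = c(0.25, 0.5, 1.0))
  p1 <- base; p1$weight[1] <- 0.25 * 1.10
  p2 <- base; p2$weight[1] <- 0.25 * 1.30
  sz <- data.frame(low_hz  = c(1,   8,   16),
                   high_hz = c(8,  16,   64),
                   weight  = c(1.0, 0.4, 0.15))
  list(
    interictal  = spectral_profile("interictal",  base),
    preictal_I  = spectral_profile("preictal_I",  p1),
    preictal_II = spectral_profile("preictal_II", p2),
    seizure     = spectral_profile("seizure",     sz)
  )
}

#' Synthetic EEG generator configuration
#'
#' @param n_channels Number of EEG channels (default 23, scalp montage size).
#' @param sampling_rate Sampling rate in Hz (default 256).
#' @param seed Integer master seed; every random draw in the generator derives
#'   from it by fixed offsets, so output is byte-identical across runs.
#' @param profiles Named list with one [spectral_profile()] per state.
#' @param seizure_intervals Numeric matrix / data frame of (onset_s, offset_s)
#'   rows, or NULL for a seizure-free recording.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_channels = 23, sampling_rate = 256, seed = 1L,
                         profiles = default_profiles(),
                         seizure_intervals = NULL) {
  stopifnot(is_count(n_channels), sampling_rate > 0)
  iv <- normalize_intervals(seizure_intervals)
  if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2]))
    stopf("seizure intervals must be non-overlapping")
  missing <- setdiff(state_labels(), names(profiles))
  if (length(missing))
    stopf("profiles missing for state(s): %s", paste(missing, collapse = ", "))
  nyq <- sampling_rate / 2
  for (p in profiles)
    if (any(p$bands$high_hz > nyq))
      stopf("profile band edge above Nyquist (%g Hz)", nyq)
  structure(list(n_channels = as.integer(n_channels),
                 sampling_rate = sampling_rate, seed = as.integer(seed),
                 profiles = profiles, seizure_intervals = iv),
            class = "synth_config")
}

normalize_intervals <- function(x) {
  if (is.null(x) || (is.matrix(x) && nrow(x) == 0))
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("onset_s", "offset_s"))))
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  stopifnot(ncol(x) == 2)
  if (any(x[, 2] <= x[, 1])) stopf("seizure offsets must exceed onsets")
  x <- x[order(x[, 1]), , drop = FALSE]
  colnames(x) <- c("onset_s", "offset_s")
  x
}

# one band-limited unit-variance noise component: seeded white Gaussian noise
# passed through an ideal (FFT brick-wall) bandpass; DC is always removed
bandlimited_noise <- function(n, fs, low, high) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                 # two-sided frequency magnitude
  keep <- f >= low & f < high
  keep[1] <- FALSE
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y / s else y
}

synth_channel <- function(profile, n, fs, seed) {
  with_seed(seed, {
    y <- numeric(n)
    bd <- profile$bands
    for (k in seq_len(nrow(bd))) {
      if (bd$weight[k] > 0)
        y <- y + sqrt(bd$weight[k]) *
          bandlimited_noise(n, fs, bd$low_hz[k], bd$high_hz[k])
    }
    if (profile$noise_floor > 0)
      y <- y + sqrt(profile$noise_floor) * stats::rnorm(n)
    y
  })
}

add_tones <- function(y, profile, fs, t0 = 0) {
  tn <- profile$tones
  if (is.null(tn) || nrow(tn) == 0) return(y)
  t <- (seq_along(y) - 1) / fs + t0
  for (k in seq_len(nrow(tn)))
    y <- y + tn$amplitude[k] * sin(2 * pi * tn$freq_hz[k] * t)
  y
}

#' Generate one labeled multichannel frame of a given epileptic state
#'
#' Each channel is an independent realization of the state's spectral profile
#' (band-limited noise mixture plus broadband floor plus any deterministic
#' tones). Fully deterministic given `config$seed` and `frame_index`.
#'
#' @param state One of [state_labels()].
#' @param config A [synth_config()].
#' @param duration_s Frame length in seconds (> 0; default 4).
#' @param frame_index Integer >= 0 distinguishing successive frames drawn from
#'   the same config (offsets the random stream).
#' @return A [labeled_frame()] with `n_channels x duration_s*fs` samples.
#' @export
generate_state_frame <- function(state, config, duration_s = 4, frame_index = 0L) {
  check_state(state)
  stopifnot(inherits(config, "synth_config"), duration_s > 0)
  fs <- config$sampling_rate
  n <- round(duration_s * fs)
  profile <- config$profiles[[state]]
  base <- config$seed + 1009L * as.integer(frame_index) +
    31L * match(state, state_labels())
  samples <- matrix(0, config$n_channels, n)
  for (ch in seq_len(config$n_channels)) {
    y <- synth_channel(profile, n, fs, base + 7919L * ch)
    samples[ch, ] <- add_tones(y, profile, fs)
  }
  labeled_frame(samples, state, t_start_s = 0,
                source_id = sprintf("synth-%s-%d", state, frame_index),
                sampling_rate = fs)
}

# per-second content map: which profile generates each second of a recording.
# Precedence seizure > preictal II > preictal I > interictal; window lengths
# follow the labeling defaults so generated content round-trips through
# assign_state().
content_states <- function(duration_s, intervals,
                           preictal_II_s = 600, preictal_I_s = 1800) {
  st <- rep("interictal", duration_s)
  sec0 <- seq_len(duration_s) - 1  # second i covers [i-1, i)
  for (k in seq_len(nrow(intervals))) {
    on <- intervals[k, 1]; off <- intervals[k, 2]
    st[sec0 >= on - preictal_I_s & sec0 < on - preictal_II_s & st == "interictal"] <- "preictal_I"
    st[sec0 >= on - preictal_II_s & sec0 < on & st != "seizure"] <- "preictal_II"
    st[sec0 >= on & sec0 < off] <- "seizure"
  }
  st
}

#' Generate a full synthetic EEG recording
#'
#' Samples inside each seizure interval follow the seizure profile; the 10 and
#' 30 minute windows before each onset carry the preictal II and preictal I
#' profiles; everything else is interictal content, so that re-labeling the
#' recording with [assign_state()] under default windows reproduces the
#' generation plan.
#'
#' @param config A [synth_config()] (its `seizure_intervals` drive the plan).
#' @param duration_s Total duration in whole seconds; must cover all intervals.
#' @return An [eeg_recording()].
#' @export
generate_recording <- function(config, duration_s) {
  stopifnot(inherits(config, "synth_config"), duration_s > 0)
  duration_s <- as.integer(duration_s)
  iv <- config$seizure_intervals
  if (nrow(iv) && any(iv[, 2] > duration_s))
    stopf("seizure interval extends beyond the %d s recording", duration_s)
  fs <- config$sampling_rate
  st <- content_states(duration_s, iv)
  runs <- rle(st)
  ends <- cumsum(runs$lengths)
  starts <- c(0, ends[-length(ends)])
  samples <- matrix(0, config$n_channels, duration_s * fs)
  for (ch in seq_len(config$n_channels)) {
    for (g in seq_along(runs$values)) {
      profile <- config$profiles[[runs$values[g]]]
      n <- runs$lengths[g] * fs
      seed <- config$seed + 7919L * ch + 131L * g
      y <- synth_channel(profile, n, fs, seed)
      y <- add_tones(y, profile, fs, t0 = starts[g])
      samples[ch, (starts[g] * fs + 1):(ends[g] * fs)] <- y
    }
  }
  eeg_recording(samples, fs,
                channel_names = sprintf("EEG %02d", seq_len(config$n_channels)),
                seizure_intervals = iv)
}
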