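test_that("frame generation is deterministic given config and seed", {
  cfg <- small_config(seed = 42)
  f1 <- generate_state_frame("preictal_I", cfg, frame_index = 3)
  f2 <- generate_state_frame("preictal_I", cfg, frame_index = 3)
  expect_identical(f1$samples, f2$samples)
  f3 <- generate_state_frame("preictal_I", cfg, frame_index = 4)
  expect_false(identical(f1$samples, f3$samples))
})

test_that("unknown state labels are rejected with the valid set named", {
  cfg <- small_config()
  expect_error(generate_state_frame("ictal", cfg), "interictal")
  expect_error(spectral_profile("postictal", data.frame(
    low_hz = 1, high_hz = 8, weight = 1)), "preictal_II")
})

test_that("a noiseless single-tone profile yields a pure sinusoid on every channel", {
  pr <- default_profiles()
  pr$seizure <- spectral_profile("seizure",
    data.frame(low_hz = 1, high_hz = 8, weight = 0), noise_floor = 0,
    tones = data.frame(freq_hz = 4, amplitude = 1))
  cfg <- small_config(seed = 1, n_channels = 3, profiles = pr)
  f <- generate_state_frame("seizure", cfg)
  t <- (0:1023) / 256
  for (ch in 1:3)
    expect_equal(f$samples[ch, ], sin(2 * pi * 4 * t), tolerance = 1e-12)
})

test_that("profiles with no positive-power component are rejected", {
  expect_error(spectral_profile("seizure",
    data.frame(low_hz = 1, high_hz = 8, weight = 0), noise_floor = 0),
    "positive power")
  expect_error(spectral_profile("seizure",
    data.frame(low_hz = 8, high_hz = 4, weight = 1)), "low < high")
})

test_that("seizure frames carry more low-frequency energy than interictal, frame by frame", {
  cfg <- synth_config(seed = 11)  # full 23-channel, 256 Hz study conditions
  lowfrac <- function(st, i) {
    f <- generate_state_frame(st, cfg, frame_index = i)
    e <- colMeans(build_psded(f)$raw_energies)  # 32 x 4-Hz bands
    sum(e[1:2]) / sum(e)
  }
  n <- 100
  sz <- vapply(seq_len(n), function(i) lowfrac("seizure", i), 0)
  ii <- vapply(seq_len(n), function(i) lowfrac("interictal", i), 0)
  expect_true(all(sz > ii))
})

test_that("mean low-band energy orders seizure > preictal II > preictal I > interictal", {
  cfg <- synth_config(seed = 5)
  low <- function(st, i) {
    f <- generate_state_frame(st, cfg, frame_index = i)
    sum(colMeans(build_psded(f)$raw_energies)[1:2])
  }
  n <- 30
  ok <- vapply(seq_len(n), function(i) {
    v <- vapply(state_labels(), low, 0, i = i)
    v["seizure"] > v["preictal_II"] && v["preictal_II"] > v["preictal_I"] &&
      v["preictal_I"] > v["interictal"]
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("default profiles are nearest-centroid separable on 32-band energy vectors", {
  cfg <- synth_config(seed = 21)
  frames <- gen_frames(cfg, 50)
  labs <- frame_labels(frames)
  X <- log10(t(vapply(frames, function(f)
    colMeans(build_psded(f)$raw_energies), numeric(32))) + 1e-12)
  cent <- sapply(state_labels(), function(s)
    colMeans(X[labs == s, , drop = FALSE]))
  pred <- state_labels()[apply(X, 1, function(v)
    which.min(colSums((cent - v)^2)))]
  expect_gte(mean(pred == as.character(labs)), 0.95)
})

test_that("recordings place state-specific content at the labeling windows", {
  cfg <- small_config(seed = 9, seizure_intervals = rbind(c(3000, 3060)))
  rec <- generate_recording(cfg, 3700)
  expect_equal(dim(rec$samples), c(4, 3700 * 256))
  lowfrac_seg <- function(a, b) {
    seg <- labeled_frame(rec$samples[, (a * 256 + 1):(b * 256)], "interictal",
                         sampling_rate = 256)
    e <- colMeans(build_psded(seg)$raw_energies)
    sum(e[1:2]) / sum(e)
  }
  # preictal II content in (2400, 3000); seizure inside the interval; baseline
  # far before: low-band fractions must be strictly ordered accordingly
  f_pre2 <- lowfrac_seg(2500, 2900)
  f_seiz <- lowfrac_seg(3005, 3055)
  f_inter <- lowfrac_seg(100, 500)
  expect_gt(f_seiz, f_pre2)
  expect_gt(f_pre2, f_inter)
})

test_that("recording generation is reproducible and validates intervals", {
  cfg <- small_config(seed = 2, n_channels = 2,
                      seizure_intervals = rbind(c(50, 70)))
  r1 <- generate_recording(cfg, 100)
  r2 <- generate_recording(cfg, 100)
  expect_identical(r1$samples, r2$samples)
  expect_error(generate_recording(cfg, 60), "beyond")
  expect_error(synth_config(seizure_intervals = rbind(c(10, 30), c(20, 40))),
               "non-overlapping")
})
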