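test_that("db6 analysis step matches the reference wavelet transform", {
  # frozen oracle: PyWavelets db6, mode='symmetric', on a fixed 32-sample mix
  x <- sin(2 * pi * 3 * (0:31) / 32) + 0.1 * cos(2 * pi * 9 * (0:31) / 32)
  s <- eegstates:::dwt_step(x, eegstates:::wavelet_filters("db6"))
  expect_equal(s$cA[1:5],
               c(-1.3011944787837308, -0.2480982413746636, 1.3059178993993472,
                 0.952730217549914, 0.11877377606938636), tolerance = 1e-12)
  expect_equal(s$cD[1:5],
               c(0.05652462195070686, -0.1475045297094002, -0.00774642433063659,
                 0.11015242582284347, -0.11060773143704634), tolerance = 1e-12)
  expect_length(s$cA, 21)
})

test_that("multilevel decomposition reconstructs perfectly without thresholding", {
  set.seed(8)
  for (n in c(256, 300, 1024)) {
    x <- rnorm(n)
    dec <- eegstates:::wavedec(x, "db6", 4)
    expect_equal(eegstates:::waverec(dec), x, tolerance = 1e-10)
  }
})

test_that("denoising degenerate and canonical inputs behaves as specified", {
  expect_equal(denoise_dwt(numeric(1024)), numeric(1024))
  # noiseless low-frequency sinusoid survives nearly unchanged
  x <- sin(2 * pi * 2 * (0:1023) / 256)
  dn <- denoise_dwt(x, levels = 5)
  expect_lt(sqrt(sum((dn - x)^2) / sum(x^2)), 0.05)
})

test_that("pure noise is strongly suppressed (worst case over 50 seeds)", {
  worst <- 0
  for (s in 1:50) {
    x <- withr::with_seed(s, rnorm(1024))
    worst <- max(worst, var(denoise_dwt(x)) / var(x))
  }
  expect_lt(worst, 0.2)
})

test_that("soft thresholding never increases signal energy", {
  for (s in 1:10) {
    x <- withr::with_seed(100 + s,
                          rnorm(512) + sin(2 * pi * 5 * (0:511) / 256) * s / 3)
    expect_lte(sum(denoise_dwt(x)^2), sum(x^2) * (1 + 1e-8))
  }
})

test_that("denoising is channel-wise: permuting channels commutes", {
  cfg <- small_config(seed = 12)
  rec <- generate_recording(cfg, 16)
  perm <- c(3, 1, 4, 2)
  a <- denoise_recording(rec)$samples[perm, ]
  permuted <- rec
  permuted$samples <- rec$samples[perm, ]
  b <- denoise_recording(permuted)$samples
  expect_identical(a, b)
})

test_that("infeasible decomposition depth reports the maximum level", {
  expect_error(denoise_dwt(rnorm(16), levels = 5), "maximum feasible level")
  expect_error(eegstates:::wavelet_filters("haar"), "db6")
})

test_that("frame counts follow floor((T - L)/S) + 1 in both regimes", {
  lw <- label_windows()
  sz <- eeg_recording(matrix(0, 1, 64 * 256), 256,
                      seizure_intervals = rbind(c(0, 60)))
  fr <- segment_frames(sz, lw)
  expect_equal(sum(frame_labels(fr) == "seizure"), 29)   # floor((60-4)/2)+1
  ns <- eeg_recording(matrix(0, 1, 60 * 256), 256)
  expect_length(segment_frames(ns, lw), 15)              # floor((60-4)/4)+1
  expect_length(segment_frames(eeg_recording(matrix(0, 1, 3 * 256), 256), lw), 0)
})

test_that("frame counts match a brute-force enumerator on random spans", {
  brute <- function(T, L, S) {
    n <- 0; t0 <- 0
    while (t0 + L <= T) { n <- n + 1; t0 <- t0 + S }
    n
  }
  set.seed(77)
  for (i in 1:50) {
    L <- sample(c(2, 4, 8), 1)
    T <- L + sample(0:97, 1)
    S <- sample(1:5, 1)
    rec <- eeg_recording(matrix(0, 1, T * 16), 16)
    fr <- segment_frames(rec, label_windows(), frame_s = L,
                         nonseizure_step_s = S)
    expect_length(fr, brute(T, L, S))
  }
})

test_that("frames carry the source samples and metadata", {
  cfg <- small_config(seed = 31, seizure_intervals = rbind(c(20, 40)))
  rec <- generate_recording(cfg, 64)
  fr <- segment_frames(rec, label_windows(min_seizure_s = 10), source_id = "r1")
  labs <- frame_labels(fr)
  # pre-onset frames are late preictal; in-seizure frames overlap by 2 s
  expect_equal(sum(labs == "preictal_II"), 5)
  expect_equal(sum(labs == "seizure"), 9)
  f <- fr[[which(labs == "seizure")[1]]]
  expect_equal(f$samples,
               rec$samples[, (f$t_start_s * 256 + 1):((f$t_start_s + 4) * 256)])
  expect_equal(f$source_id, "r1")
})
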