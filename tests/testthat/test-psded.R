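test_that("periodogram satisfies the discrete Parseval identity", {
  for (s in 1:5) {
    x <- withr::with_seed(s, rnorm(1024))
    pg <- periodogram_psd(x, 256)
    expect_equal(sum(pg$psd) * (pg$freq[2] - pg$freq[1]), mean(x^2),
                 tolerance = 1e-10)
  }
  x <- withr::with_seed(1, rnorm(333))  # odd length
  pg <- periodogram_psd(x, 100)
  expect_equal(sum(pg$psd) * (pg$freq[2] - pg$freq[1]), mean(x^2),
               tolerance = 1e-10)
})

test_that("a unit 10 Hz tone concentrates its 0.5 total power near 10 Hz", {
  t <- (0:1023) / 256
  pg <- periodogram_psd(sin(2 * pi * 10 * t), 256)
  df <- pg$freq[2] - pg$freq[1]
  total <- sum(pg$psd) * df
  expect_equal(total, 0.5, tolerance = 1e-6)
  near <- abs(pg$freq - 10) <= 0.5
  expect_gte(sum(pg$psd[near]) / sum(pg$psd), 0.99)
})

test_that("degenerate periodogram inputs behave", {
  pg <- periodogram_psd(numeric(64), 256)
  expect_true(all(pg$psd == 0))
  expect_error(periodogram_psd(rnorm(64), -1), "positive")
})

test_that("white noise integrated PSD estimates unit variance", {
  m <- vapply(1:100, function(s) {
    x <- withr::with_seed(1000 + s, rnorm(1024))
    pg <- periodogram_psd(x, 256)
    sum(pg$psd) * (pg$freq[2] - pg$freq[1])
  }, 0)
  se <- sqrt(2 / 1024) / sqrt(100)   # var(x^2) = 2 for standard normal
  expect_lt(abs(mean(m) - 1), 3 * se)
})

test_that("band energies partition the spectrum exactly", {
  x <- withr::with_seed(3, rnorm(1024))
  pg <- periodogram_psd(x, 256)
  df <- pg$freq[2] - pg$freq[1]
  be <- band_energies(pg$freq, pg$psd, band_edges(32, 256))
  expect_length(be, 32)
  expect_equal(sum(be), sum(pg$psd) * df, tolerance = 1e-14)
  expect_equal(band_energies(pg$freq, pg$psd * 0, band_edges(32, 256)),
               numeric(32))
  expect_error(band_energies(pg$freq, pg$psd, c(0, 200)), "within")
  expect_error(band_energies(pg$freq, pg$psd, c(8, 4, 16)), "ascending")
})

test_that("a 10 Hz tone lands in the 8-12 Hz band", {
  t <- (0:1023) / 256
  pg <- periodogram_psd(sin(2 * pi * 10 * t), 256)
  be <- band_energies(pg$freq, pg$psd, band_edges(32, 256))
  expect_gte(be[3] / sum(be), 0.99)   # bands: [0,4), [4,8), [8,12) ...
})

test_that("PSDED has n x 32 shape, unit range, and localizes a tone", {
  cfg <- synth_config(seed = 2)
  f <- generate_state_frame("interictal", cfg)
  p <- build_psded(f)
  expect_equal(dim(p$energies), c(23, 32))
  expect_equal(range(p$energies), c(0, 1))
  expect_length(p$band_edges_hz, 33)

  m <- matrix(0, 3, 1024)
  m[1, ] <- sin(2 * pi * 4 * (0:1023) / 256)
  p2 <- build_psded(labeled_frame(m, "seizure", sampling_rate = 256))
  peak <- which(p2$energies == 1, arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(1, 2))  # channel 1, 4-8 Hz band
})

test_that("normalized PSDED is invariant to overall signal amplitude", {
  cfg <- small_config(seed = 6)
  f <- generate_state_frame("preictal_II", cfg)
  f10 <- f
  f10$samples <- f$samples * 10
  expect_equal(build_psded(f)$energies, build_psded(f10)$energies,
               tolerance = 1e-9)
})

test_that("a constant-energy frame degenerates to an all-zero diagram", {
  f <- labeled_frame(matrix(0, 2, 512), "interictal", sampling_rate = 128)
  expect_true(all(build_psded(f)$energies == 0))
})

test_that("seizure diagrams hold more low-band mass than interictal ones", {
  cfg <- synth_config(seed = 14)
  ok <- vapply(1:30, function(i) {
    lm <- function(st) {
      e <- build_psded(generate_state_frame(st, cfg, frame_index = i))$energies
      mean(e[, 1:2])
    }
    lm("seizure") > lm("interictal")
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("rendering produces backbone-sized 8-bit images", {
  cfg <- small_config(seed = 8)
  p <- build_psded(generate_state_frame("seizure", cfg))
  img <- render_image(p, 299)
  expect_equal(dim(img$pixels), c(299, 299, 3))
  expect_true(all(img$pixels >= 0 & img$pixels <= 255))
  expect_identical(img$pixels[, , 1], img$pixels[, , 3])
  expect_error(render_image(p, 0), "positive")

  const <- p
  const$energies[] <- 0.5
  gray <- render_image(const, 32)
  expect_true(all(gray$pixels == 128))

  # nearest-neighbor at the native size is the identity up to 8-bit rounding
  rt <- render_image(p, c(nrow(p$energies), ncol(p$energies)), "nearest")
  expect_equal(rt$pixels[, , 1], round(p$energies * 255),
               ignore_attr = TRUE)
})

test_that("PSDED datasets round-trip through PNG tiles and manifest", {
  cfg <- small_config(seed = 13)
  frames <- gen_frames(cfg, 2)
  dir <- withr::local_tempdir()
  manifest <- write_psded_dataset(frames, dir, size = 24)
  expect_equal(nrow(manifest), 8)
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  ds <- read_psded_dataset(dir)
  expect_equal(dim(ds$images), c(24, 24, 3, 8))
  expect_equal(as.character(ds$labels), manifest$label)
  expect_equal(sort(as.character(unique(ds$labels))), sort(state_labels()))
})
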