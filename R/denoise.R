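# db6 analysis lowpass filter (order-6 Daubechies); the other three filter
# bank members follow by quadrature mirror / time reversal.
DB6_DEC_LO <- c(
  -0.0010773010853084796, 0.004777257510945511, 0.0005538422011614961,
  -0.03158203931748603, 0.027522865530305727, 0.09750160558732304,
  -0.12976686756726194, -0.22626469396543983, 0.31525035170919763,
  0.7511339080210954, 0.49462389039845306, 0.11154074335010947)

wavelet_filters <- function(wavelet = "db6") {
  if (!identical(wavelet, "db6"))
    stopf("only the db6 wavelet is implemented (got '%s')", wavelet)
  lo <- DB6_DEC_LO
  hi <- rev(lo) * (-1)^seq_along(lo)
  list(dec_lo = lo, dec_hi = hi, rec_lo = rev(lo), rec_hi = rev(hi),
       len = length(lo))
}

# valid convolution sum_m f[m] x[i+m-1] (C-level, no large temporaries)
conv_valid <- function(x, f) {
  y <- stats::filter(x, rev(f), method = "convolution", sides = 1)
  as.numeric(y[length(f):length(x)])
}

conv_full <- function(x, f) {
  z <- numeric(length(f) - 1)
  conv_valid(c(z, x, z), rev(f))
}

# single-level DWT with half-point symmetric boundary extension
dwt_step <- function(x, flt) {
  F <- flt$len
  n <- length(x)
  ext <- c(rev(x[seq_len(F - 1)]), x, rev(x[(n - F + 2):n]))
  keep <- seq(2, n + F - 1, by = 2)
  vA <- conv_valid(ext, rev(flt$dec_lo))
  vD <- conv_valid(ext, rev(flt$dec_hi))
  list(cA = vA[keep], cD = vD[keep])
}

idwt_step <- function(cA, cD, flt, out_len) {
  F <- flt$len
  L <- length(cA)
  up <- function(cf) { u <- numeric(2 * L); u[seq(1, 2 * L, 2)] <- cf; u }
  r <- conv_full(up(cA), flt$rec_lo) + conv_full(up(cD), flt$rec_hi)
  r[(F - 1):(F - 2 + out_len)]
}

# multilevel decomposition; returns approximation + per-level details and the
# signal length at each level (needed to trim the synthesis pass)
wavedec <- function(x, wavelet = "db6", levels = 5) {
  flt <- wavelet_filters(wavelet)
  stopifnot(is_count(levels))
  if (length(x) < 2^levels)
    stopf("signal of length %d is too short for %d levels; maximum feasible level is %d",
          length(x), levels, max(0L, floor(log2(length(x)))))
  details <- vector("list", levels)
  lens <- integer(levels)
  cur <- x
  for (j in seq_len(levels)) {
    lens[j] <- length(cur)
    s <- dwt_step(cur, flt)
    details[[j]] <- s$cD  # details[[1]] = finest scale
    cur <- s$cA
  }
  list(cA = cur, details = details, lens = lens, wavelet = wavelet)
}

waverec <- function(dec) {
  flt <- wavelet_filters(dec$wavelet)
  cur <- dec$cA
  for (j in rev(seq_along(dec$details)))
    cur <- idwt_step(cur, dec$details[[j]], flt, dec$lens[j])
  cur
}

#' Wavelet threshold denoising of a single-channel signal
#'
#' Decomposes the signal with a db6 discrete wavelet transform (symmetric
#' boundary extension), thresholds all detail coefficients with the universal
#' threshold `sigma * sqrt(2 * log(N))` where `sigma` is estimated from the
#' finest-scale details as `median(|d1|) / 0.6745`, and reconstructs.
#'
#' @param x Numeric vector, length at least `2^levels`.
#' @param wavelet Mother wavelet name (only `"db6"`).
#' @param levels Decomposition depth (default 5; at 256 Hz the finest detail
#'   band is ~64-128 Hz, so five levels reach the low EEG rhythms).
#' @param threshold_mode `"soft"` (default; shrinks coefficients toward zero)
#'   or `"hard"` (zeroes sub-threshold coefficients only).
#' @return Denoised signal, same length as `x`.
#' @export
denoise_dwt <- function(x, wavelet = "db6", levels = 5,
                        threshold_mode = c("soft", "hard")) {
  threshold_mode <- match.arg(threshold_mode)
  x <- as.numeric(x)
  dec <- wavedec(x, wavelet, levels)
  sigma <- stats::median(abs(dec$details[[1]])) / 0.6745
  thr <- sigma * sqrt(2 * log(length(x)))
  dec$details <- lapply(dec$details, function(d) {
    if (threshold_mode == "soft") sign(d) * pmax(abs(d) - thr, 0)
    else d * (abs(d) > thr)
  })
  waverec(dec)
}

#' Denoise every channel of a recording
#'
#' Channel-wise [denoise_dwt()] over the whole recording (before framing, so
#' frames carry no thresholding edge artifacts).
#'
#' @param recording An [eeg_recording()].
#' @inheritParams denoise_dwt
#' @return A new [eeg_recording()] with denoised samples.
#' @export
denoise_recording <- function(recording, wavelet = "db6", levels = 5,
                              threshold_mode = "soft") {
  stopifnot(inherits(recording, "eeg_recording"))
  out <- recording
  for (ch in seq_len(nrow(out$samples)))
    out$samples[ch, ] <- denoise_dwt(out$samples[ch, ], wavelet, levels,
                                     threshold_mode)
  out
}
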