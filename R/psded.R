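#' One-sided periodogram power spectral density estimate
#'
#' Plain (rectangular-window) periodogram with density scaling, so that
#' `sum(psd) * delta_f` equals the mean squared signal value exactly
#' (discrete Parseval identity).
#'
#' @param x Numeric signal vector, length >= 2.
#' @param fs Sampling rate in Hz (> 0).
#' @return List with `freq` (Hz, from 0 to Nyquist) and `psd` (power / Hz).
#' @export
periodogram_psd <- function(x, fs) {
  if (!(is.numeric(fs) && length(fs) == 1 && fs > 0))
    stopf("sampling rate must be a positive number")
  n <- length(x)
  stopifnot(n >= 2)
  X <- stats::fft(x)
  p <- abs(X)^2 / (n * fs)       # two-sided density
  half <- floor(n / 2) + 1L      # bins 0 .. Nyquist (n even) or < Nyquist
  psd <- p[seq_len(half)]
  if (n %% 2 == 0) {
    psd[2:(half - 1)] <- 2 * psd[2:(half - 1)]  # fold; DC and Nyquist unpaired
  } else {
    psd[2:half] <- 2 * psd[2:half]
  }
  list(freq = (seq_len(half) - 1) * fs / n, psd = psd)
}

#' Default 32 equal-width band edges over the one-sided axis
#' @param n_bands Number of bands (default 32).
#' @param fs Sampling rate in Hz (bands span 0 to `fs/2`).
#' @return Numeric vector of `n_bands + 1` ascending edges.
#' @export
band_edges <- function(n_bands = 32, fs = 256) {
  seq(0, fs / 2, length.out = n_bands + 1)
}

#' Integrate a PSD over frequency bands
#'
#' Band `j` collects `psd * delta_f` over bins with `edge_j <= f < edge_{j+1}`;
#' the final band also includes the Nyquist bin, so the bands partition the
#' spectrum and their sum equals the total integrated PSD exactly.
#'
#' @param freq,psd As returned by [periodogram_psd()].
#' @param edges Ascending band edges spanning `[0, Nyquist]`.
#' @return Numeric vector of band energies, length `length(edges) - 1`.
#' @export
band_energies <- function(freq, psd, edges) {
  stopifnot(length(freq) == length(psd), length(edges) >= 2)
  if (is.unsorted(edges, strictly = TRUE))
    stopf("band edges must be strictly ascending")
  nyq <- max(freq)
  if (edges[1] < 0 || edges[length(edges)] > nyq + 1e-9)
    stopf("band edges must lie within [0, %g] Hz", nyq)
  df <- freq[2] - freq[1]
  idx <- findInterval(freq, edges, rightmost.closed = TRUE)
  idx[idx < 1 | idx > length(edges) - 1] <- NA
  e <- vapply(seq_len(length(edges) - 1),
              function(j) sum(psd[which(idx == j)]) * df, 0)
  e
}

#' Power spectrum density energy diagram (PSDED) of a frame
#'
#' For each channel: periodogram PSD, integration over `n_bands` equal bands
#' spanning 0 to Nyquist, `log10(energy + 1e-12)` compression, then a single
#' min-max normalization over the whole matrix to `[0, 1]`. The log makes the
#' normalized diagram invariant to overall signal amplitude; a constant-energy
#' (zero-range) frame degenerates to an all-zero matrix.
#'
#' @param frame A [labeled_frame()].
#' @param n_bands Number of frequency bands (default 32).
#' @param transform `"log"` (default) or `"raw"` band energies before
#'   normalization.
#' @param normalize `"global"` (default, one min-max over the matrix) or
#'   `"per_channel"` (min-max each row separately).
#' @return Object of class `psded`: list with `energies` (normalized
#'   `n_channels x n_bands`), `raw_energies`, `band_edges_hz`, `label`.
#' @export
build_psded <- function(frame, n_bands = 32, transform = c("log", "raw"),
                        normalize = c("global", "per_channel")) {
  stopifnot(inherits(frame, "labeled_frame"))
  transform <- match.arg(transform)
  normalize <- match.arg(normalize)
  fs <- frame$sampling_rate
  edges <- band_edges(n_bands, fs)
  raw <- t(apply(frame$samples, 1, function(ch) {
    pg <- periodogram_psd(ch, fs)
    band_energies(pg$freq, pg$psd, edges)
  }))
  m <- if (transform == "log") log10(raw + 1e-12) else raw
  minmax <- function(v) {
    rng <- max(v) - min(v)
    if (rng == 0) v * 0 else (v - min(v)) / rng
  }
  energies <- if (normalize == "global") {
    matrix(minmax(as.vector(m)), nrow(m), ncol(m))
  } else {
    t(apply(m, 1, minmax))
  }
  structure(list(energies = energies, raw_energies = raw,
                 band_edges_hz = edges, label = frame$label,
                 source_id = frame$source_id, t_start_s = frame$t_start_s),
            class = "psded")
}

#' @export
print.psded <- function(x, ...) {
  cat(sprintf("<psded> %d channels x %d bands (0-%g Hz), label = %s\n",
              nrow(x$energies), ncol(x$energies), max(x$band_edges_hz),
              x$label %||% "?"))
  invisible(x)
}

#' Render a PSDED as a classifier-ready image
#'
#' Rescales the normalized band-energy matrix to `size x size` (bilinear by
#' default), replicates it to 3 identical channels and quantizes to 8 bits.
#'
#' @param psded A [build_psded()] result.
#' @param size Target side length in pixels (e.g. 299 or 224), or a length-2
#'   `c(height, width)` vector.
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return Object of class `psded_image`: list with `pixels` (H x W x 3
#'   integer array, 0-255) and `source` metadata.
#' @export
render_image <- function(psded, size = 299,
                         interpolation = c("bilinear", "nearest")) {
  stopifnot(inherits(psded, "psded"))
  interpolation <- match.arg(interpolation)
  if (length(size) == 1) size <- c(size, size)
  if (any(size < 1)) stopf("target size must be positive")
  m <- EBImage::resize(psded$energies, w = size[1], h = size[2],
                       filter = if (interpolation == "bilinear") "bilinear" else "none")
  m <- pmin(pmax(m, 0), 1)
  q <- as.integer(round(m * 255))
  pixels <- array(q, dim = c(size[1], size[2], 3))
  structure(list(pixels = pixels, label = psded$label,
                 source_id = psded$source_id, t_start_s = psded$t_start_s,
                 resize_mode = interpolation),
            class = "psded_image")
}

#' Convert a PSDED image to a floating point tensor in [0, 1]
#' @param img A [render_image()] result.
#' @return H x W x 3 double array.
#' @export
image_tensor <- function(img) {
  stopifnot(inherits(img, "psded_image"))
  img$pixels / 255
}

#' Write a dataset of PSDED image tiles plus a TSV manifest
#'
#' One 8-bit grayscale-replicated PNG per frame, named
#' `<source_id>_<t_start>.png`, and a `manifest.tsv` with columns `path`,
#' `label`, `source_id`, `t_start_s` -- the on-disk contract consumed by the
#' training stage (and exportable to external classifiers).
#'
#' @param frames List of [labeled_frame()] objects.
#' @param out_dir Output directory (created if needed).
#' @param size Tile side length in pixels (default 64; backbones resize
#'   internally to their own input sizes).
#' @param n_bands Bands per PSDED (default 32).
#' @return Data frame manifest, invisibly; also written to
#'   `file.path(out_dir, "manifest.tsv")`.
#' @export
write_psded_dataset <- function(frames, out_dir, size = 64, n_bands = 32) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    img <- render_image(build_psded(f, n_bands), size)
    fn <- sprintf("%s_%08.1f_%04d.png", gsub("[^A-Za-z0-9_-]", "-", f$source_id),
                  f$t_start_s, i)
    png::writePNG(image_tensor(img), file.path(out_dir, fn))
    data.frame(path = fn, label = f$label, source_id = f$source_id,
               t_start_s = f$t_start_s)
  })
  manifest <- do.call(rbind, rows) %||% data.frame(
    path = character(0), label = character(0), source_id = character(0),
    t_start_s = numeric(0))
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Load a PSDED image dataset written by [write_psded_dataset()]
#'
#' @param dir Dataset directory containing `manifest.tsv` and PNG tiles.
#' @return List with `images` (H x W x 3 x N array in `[0, 1]`), `labels`
#'   (factor over [state_labels()]) and the `manifest` data frame.
#' @export
read_psded_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf)) stopf("no manifest.tsv in %s", dir)
  manifest <- utils::read.table(mf, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  if (nrow(manifest) == 0) stopf("empty dataset manifest in %s", dir)
  imgs <- lapply(manifest$path, function(p) {
    a <- png::readPNG(file.path(dir, p))
    if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
    a[, , 1:3, drop = FALSE]
  })
  d <- dim(imgs[[1]])
  images <- array(0, c(d[1], d[2], 3, length(imgs)))
  for (i in seq_along(imgs)) images[, , , i] <- imgs[[i]]
  list(images = images,
       labels = factor(manifest$label, levels = state_labels()),
       manifest = manifest)
}
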