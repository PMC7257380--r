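# Minimal EDF (European Data Format) I/O: ASCII header + 16-bit little-endian
# samples, one-second data records. Covers plain EDF as produced by
# write_edf(); EDF+ annotation channels are not parsed (seizure annotations
# travel in a sidecar text file, see read_annotations()).

edf_num8 <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d, width = 1)
    if (nchar(s) <= 8) return(s)
  }
  stopf("cannot format %g into 8 EDF header bytes", x)
}

edf_pad <- function(s, width) {
  s <- substr(s, 1, width)
  formatC(s, width = -width)  # left-justified, blank padded
}

#' Write a recording to an EDF file
#'
#' Samples are scaled per channel to the full 16-bit digital range, so the
#' round trip through [read_edf()] is exact up to the per-channel quantization
#' step `max(abs(x)) / 32767`. The recording length must be a whole number of
#' seconds. Seizure intervals, if any, are written to a sidecar annotation
#' file `<path>.ann` (see [write_annotations()]).
#'
#' @param recording An [eeg_recording()].
#' @param path Output file path.
#' @param write_sidecar Write the `<path>.ann` annotation sidecar (default TRUE).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, write_sidecar = TRUE) {
  stopifnot(inherits(recording, "eeg_recording"))
  x <- recording$samples
  fs <- recording$sampling_rate
  if (fs != round(fs)) stopf("EDF writer requires an integer sampling rate")
  ns <- nrow(x)
  if (ncol(x) %% fs != 0)
    stopf("recording length must be a whole number of seconds for EDF export")
  n_rec <- ncol(x) %/% fs

  pmax_ch <- pmax(apply(abs(x), 1, max), 1e-6)
  pmax_ch <- vapply(pmax_ch, function(p) as.numeric(edf_num8(p)), numeric(1))
  gain <- 32767 / pmax_ch
  dig <- round(x * gain)  # n_channels x n_samples integers in [-32767, 32767]

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  writeChar(paste0(
    edf_pad("0", 8), edf_pad("synthetic subject", 80),
    edf_pad("eegstates export", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(as.character(hdr_bytes), 8), edf_pad("", 44),
    edf_pad(as.character(n_rec), 8), edf_pad("1", 8),
    edf_pad(as.character(ns), 4)
  ), con, eos = NULL)
  field <- function(vals, width) paste(vapply(vals, edf_pad, "", width = width),
                                       collapse = "")
  writeChar(paste0(
    field(recording$channel_names, 16),
    field(rep("", ns), 80),
    field(rep("uV", ns), 8),
    field(vapply(-pmax_ch, edf_num8, ""), 8),
    field(vapply(pmax_ch, edf_num8, ""), 8),
    field(rep("-32767", ns), 8),
    field(rep("32767", ns), 8),
    field(rep("", ns), 80),
    field(rep(as.character(fs), ns), 8),
    field(rep("", ns), 32)
  ), con, eos = NULL)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    block <- t(dig[, cols, drop = FALSE])  # fs x ns: per signal contiguous
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  if (write_sidecar)  # an empty sidecar marks a valid seizure-free recording
    write_annotations(recording$seizure_intervals, paste0(path, ".ann"))
  invisible(path)
}

read_edf_header <- function(con) {
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  version <- rd(8); patient <- rd(80); rec <- rd(80)
  date <- rd(8); time <- rd(8)
  hdr_bytes <- as.integer(rd(8)); reserved <- rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stopf("not a valid EDF file (bad signal count)")
  per <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  list(
    n_rec = n_rec, rec_dur = rec_dur, ns = ns, hdr_bytes = hdr_bytes,
    labels = per(16), transducer = per(80), dim = per(8),
    phys_min = as.numeric(per(8)), phys_max = as.numeric(per(8)),
    dig_min = as.numeric(per(8)), dig_max = as.numeric(per(8)),
    prefilter = per(80), spr = as.integer(per(8)), reserved2 = per(32)
  )
}

#' Read an EDF file into an [eeg_recording()]
#'
#' @param path EDF file path. If a sidecar `<path>.ann` file exists, seizure
#'   intervals are read from it.
#' @param channel_subset Optional character vector of channel names to keep
#'   (in file order). Missing names are an error listing available channels.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, channel_subset = NULL) {
  if (!file.exists(path)) stopf("EDF file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_edf_header(con)
  fs <- h$spr / h$rec_dur
  if (length(unique(fs)) != 1)
    stopf("inconsistent per-channel sampling rates: %s",
          paste(unique(fs), collapse = ", "))
  fs <- fs[1]
  keep <- seq_len(h$ns)
  if (!is.null(channel_subset)) {
    if (length(channel_subset) == 0) stopf("channel_subset must be non-empty")
    miss <- setdiff(channel_subset, h$labels)
    if (length(miss))
      stopf("channel(s) not in file: %s; available: %s",
            paste(miss, collapse = ", "), paste(h$labels, collapse = ", "))
    keep <- which(h$labels %in% channel_subset)
  }
  spr <- h$spr[1]
  n_total <- h$n_rec * spr
  samples <- matrix(0, length(keep), n_total)
  gain <- (h$phys_max - h$phys_min) / (h$dig_max - h$dig_min)
  offset <- h$phys_min - gain * h$dig_min
  for (r in seq_len(h$n_rec)) {
    block <- readBin(con, integer(), n = sum(h$spr), size = 2,
                     endian = "little")
    block <- matrix(block, spr, h$ns)
    cols <- ((r - 1) * spr + 1):(r * spr)
    samples[, cols] <- t(block[, keep, drop = FALSE] *
                           rep(gain[keep], each = spr) +
                           rep(offset[keep], each = spr))
  }
  ann <- paste0(path, ".ann")
  iv <- if (file.exists(ann)) read_annotations(ann) else NULL
  eeg_recording(samples, fs, channel_names = h$labels[keep],
                seizure_intervals = iv)
}

#' Write seizure annotations as a sidecar text file
#'
#' One `onset_s<TAB>offset_s` line per seizure, mirroring summary-file style
#' annotation distribution used with scalp-EEG databases.
#'
#' @param intervals Matrix / data frame of (onset_s, offset_s) rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(intervals, path) {
  iv <- normalize_intervals(intervals)
  utils::write.table(iv, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a seizure annotation sidecar file
#' @param path Path to a file of `onset_s<TAB>offset_s` lines.
#' @return Matrix with columns onset_s, offset_s (0 rows if file is empty).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  if (file.size(path) == 0) return(normalize_intervals(NULL))
  x <- utils::read.table(path, sep = "\t", header = FALSE)
  normalize_intervals(x)
}
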