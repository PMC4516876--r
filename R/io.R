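# File I/O: EDF recordings, tab-separated annotation files, and the
# 0.2-40 Hz preprocessing filter with 30-s segmentation.
#
# EDF (European Data Format) stores a 256-byte fixed-width ASCII header,
# 256 bytes of per-signal header fields, then contiguous data records of
# little-endian 16-bit integers calibrated through per-signal physical /
# digital ranges. Only continuous single-frequency EDF is supported here,
# which covers the polysomnography exports this package targets.

edf_pad <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  s
}

#' Write a single-channel recording to an EDF file
#'
#' Samples are calibrated into 16-bit integers over a symmetric physical
#' range covering the data. The record duration is 1 s with `fs` samples
#' per record; a trailing partial record is zero-padded (the reader
#' returns the padded length, so write whole seconds for exact
#' round-trips).
#'
#' @param x numeric samples in microvolts.
#' @param path output file path.
#' @param fs sampling rate in Hz (positive integer).
#' @param channel_label signal label stored in the header (default "C3").
#' @return `path`, invisibly.
#' @export
write_edf <- function(x, path, fs, channel_label = "C3") {
  if (fs != round(fs) || fs <= 0) {
    stop("`fs` must be a positive integer for EDF export", call. = FALSE)
  }
  x <- as.numeric(x)
  n_rec <- ceiling(length(x) / fs)
  x <- c(x, numeric(n_rec * fs - length(x)))
  pr <- max(abs(x), 1) * 1.0001
  dmin <- -32768; dmax <- 32767
  dig <- as.integer(pmin(pmax(round((x + pr) / (2 * pr) * (dmax - dmin) + dmin),
                              dmin), dmax))

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("synthetic", 80), edf_pad("sleepwave export", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * 2, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(1, 4),
    # per-signal fields (one signal)
    edf_pad(channel_label, 16), edf_pad("", 80), edf_pad("uV", 8),
    edf_pad(sprintf("%.6g", -pr), 8), edf_pad(sprintf("%.6g", pr), 8),
    edf_pad(dmin, 8), edf_pad(dmax, 8), edf_pad("", 80),
    edf_pad(fs, 8), edf_pad("", 32))
  writeChar(hdr, con, eos = NULL)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read one channel from an EDF file
#'
#' @param path EDF file path.
#' @param channel signal label to extract; `NULL` (default) takes the
#'   first signal.
#' @return List with `signal` (microvolts), `fs`, `channel_label`.
#' @export
read_edf <- function(path, channel = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) trimws(readChar(con, nc, useBytes = TRUE))
  version <- rd(8)
  if (!nzchar(version)) stop("malformed EDF header", call. = FALSE)
  rd(80); rd(80); rd(8); rd(8)
  num1 <- function(x) {
    v <- suppressWarnings(as.numeric(x))
    if (length(v) != 1L || is.na(v)) stop("malformed EDF header", call. = FALSE)
    v
  }
  hbytes <- num1(rd(8))
  rd(44)
  n_rec <- num1(rd(8))
  rec_dur <- num1(rd(8))
  ns <- num1(rd(4))
  if (ns < 1) stop("malformed EDF header", call. = FALSE)
  ns <- as.integer(ns)
  n_rec <- as.integer(n_rec)
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)                      # transducer
  for (i in seq_len(ns)) rd(8)                       # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)                      # prefiltering
  nsamp <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)                      # reserved

  sel <- if (is.null(channel)) 1L else match(channel, labels)
  if (is.na(sel)) {
    stop(sprintf("channel '%s' not found (available: %s)", channel,
                 paste(labels, collapse = ", ")), call. = FALSE)
  }
  per_rec <- sum(nsamp)
  raw <- readBin(con, integer(), n = n_rec * per_rec, size = 2L,
                 endian = "little")
  if (length(raw) < n_rec * per_rec) stop("truncated EDF data", call. = FALSE)
  offs <- c(0L, cumsum(nsamp))[sel]
  idx <- as.vector(outer(offs + seq_len(nsamp[sel]),
                         (seq_len(n_rec) - 1L) * per_rec, "+"))
  dig <- raw[idx]
  phys <- (dig - dmin_[sel]) * (pmax_[sel] - pmin_[sel]) /
    (dmax_[sel] - dmin_[sel]) + pmin_[sel]
  list(signal = phys, fs = nsamp[sel] / rec_dur, channel_label = labels[sel])
}

#' Write events to a tab-separated annotation file
#'
#' Columns: `segment` (1-based), `event_type`, `start_s`, `end_s`,
#' `start_sample`, `end_sample` (0-based, half-open). Reading the file
#' back with [read_annotations()] restores the event table.
#'
#' @param events an [sw_events()] table.
#' @param path output path.
#' @param fs sampling rate used for the sample columns.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(events, path, fs) {
  df <- data.frame(segment = events$segment_id,
                   event_type = events$kind,
                   start_s = sprintf("%.6f", events$start_s),
                   end_s = sprintf("%.6f", events$end_s),
                   start_sample = round(events$start_s * fs),
                   end_sample = round(events$end_s * fs))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated annotation file
#'
#' @param path annotation file written by [write_annotations()] (or by
#'   hand with the same columns).
#' @return An [sw_events()] table.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  if (length(lines) <= 1L) return(sw_events())
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  need <- c("segment", "event_type", "start_s", "end_s")
  if (!all(need %in% header)) {
    stop("annotation file must have columns segment, event_type, start_s, end_s",
         call. = FALSE)
  }
  rows <- lapply(seq_along(lines)[-1L], function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != length(header)) {
      stop(sprintf("malformed annotation row at line %d of %s", i, path),
           call. = FALSE)
    }
    v <- stats::setNames(as.list(f), header)
    seg <- suppressWarnings(as.integer(v$segment))
    st <- suppressWarnings(as.numeric(v$start_s))
    en <- suppressWarnings(as.numeric(v$end_s))
    if (anyNA(c(seg, st, en)) || !v$event_type %in% c("spindle", "kcomplex")) {
      stop(sprintf("malformed annotation row at line %d of %s", i, path),
           call. = FALSE)
    }
    data.frame(kind = v$event_type, segment_id = seg, start_s = st, end_s = en)
  })
  df <- do.call(rbind, rows)
  sw_events(df$kind, df$segment_id, df$start_s, df$end_s)
}

#' Artifact-rejection band-pass preprocessing
#'
#' Zero-phase 0.2-40 Hz FIR band-pass, the standard artifact-reduction
#' step before decomposition; length is preserved.
#'
#' @param x raw EEG in microvolts.
#' @param fs sampling rate in Hz.
#' @param low,high cutoff frequencies in Hz (defaults 0.2 and 40).
#' @return Filtered signal, same length.
#' @export
preprocess <- function(x, fs, low = 0.2, high = 40) {
  bandpass(as.numeric(x), fs, low, high)
}

#' Split a recording into consecutive 30-s segments
#'
#' Half-open windows; a trailing partial window is dropped.
#'
#' @param n number of samples.
#' @param fs sampling rate in Hz.
#' @param segment_s window length in seconds (default 30).
#' @return List of integer index vectors, one per segment.
#' @export
segment_indices <- function(n, fs, segment_s = 30) {
  seg_n <- round(segment_s * fs)
  k <- floor(n / seg_n)
  lapply(seq_len(k), function(i) ((i - 1L) * seg_n + 1L):(i * seg_n))
}
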