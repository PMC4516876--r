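# K-complex detection.
#
# A K-complex is a well delineated negative sharp wave immediately
# followed by a positive component, total duration >= 0.5 s. The
# transient component of the decomposition is band-pass filtered to
# 0.5-5 Hz to suppress residual fast activity whose local minima could
# mimic K-complex troughs, then troughs (strict local minima) at or below
# a negative amplitude threshold become events, with successive detected
# troughs constrained to be at least 2 s apart (the shallower of any
# closer pair is dropped).

#' K-complex detector configuration
#'
#' @param band_low,band_high FIR band edges in Hz (defaults 0.5 and 5).
#' @param threshold detection threshold in microvolts, strictly negative
#'   (default -70).
#' @param min_separation_s minimum separation between detected troughs in
#'   seconds (default 2).
#' @param n_taps FIR length; `NULL` uses the [fir_bandpass_design()]
#'   default for the band.
#' @param min_duration_s AASM duration floor for the event extent
#'   (default 0.5 s).
#' @return Object of class `kc_config`.
#' @export
kc_config <- function(band_low = 0.5, band_high = 5, threshold = -70,
                      min_separation_s = 2, n_taps = NULL,
                      min_duration_s = 0.5) {
  if (!is.numeric(threshold) || threshold >= 0) {
    stop("`threshold` must be strictly negative (microvolts)", call. = FALSE)
  }
  if (band_low <= 0 || band_high <= band_low) {
    stop("need 0 < band_low < band_high", call. = FALSE)
  }
  if (min_separation_s < 0) stop("`min_separation_s` must be >= 0", call. = FALSE)
  structure(list(band_low = band_low, band_high = band_high,
                 threshold = threshold, min_separation_s = min_separation_s,
                 n_taps = n_taps, min_duration_s = min_duration_s),
            class = "kc_config")
}

#' Band-pass the transient component for K-complex detection
#'
#' Zero-phase FIR band-pass (0.5-5 Hz by default), preserving trough
#' timing; output length equals input length.
#'
#' @param x transient component, microvolts.
#' @param fs sampling rate in Hz; must exceed `2 * band_high`.
#' @param cfg a [kc_config()].
#' @return Filtered signal.
#' @export
kc_bandpass <- function(x, fs, cfg = kc_config()) {
  stopifnot(inherits(cfg, "kc_config"))
  bandpass(x, fs, cfg$band_low, cfg$band_high, cfg$n_taps)
}

#' Strict local minima of a signal
#'
#' `x[i]` is reported when `x[i] < x[i-1]` and `x[i] < x[i+1]`; endpoints
#' and plateaus are never minima.
#'
#' @param x numeric vector, length >= 3.
#' @return `data.frame` with `index` and `value`.
#' @export
local_minima_1d <- function(x) {
  if (length(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  i <- 2L:(length(x) - 1L)
  sel <- x[i] < x[i - 1L] & x[i] < x[i + 1L]
  data.frame(index = i[sel], value = x[i][sel])
}

#' Detect K-complexes in a filtered transient component
#'
#' Strict local minima at or below the (negative) threshold are candidate
#' troughs. When two candidates are closer than `min_separation_s`, the
#' more negative one is kept. The event extent runs from the last
#' zero-crossing before the trough to the first zero-crossing after the
#' following positive peak; if crossings are missing, trough +/- 0.75 s
#' is used; extents shorter than the duration floor are widened
#' symmetrically around the trough.
#'
#' @param xf transient component already filtered by [kc_bandpass()]
#'   (microvolts).
#' @param fs sampling rate in Hz.
#' @param cfg a [kc_config()]; `cfg$threshold` must be negative.
#' @param segment_id optional segment label for the event table.
#' @return An [sw_events()] table of K-complexes; `peak_value` is the
#'   trough amplitude in microvolts.
#' @export
detect_kcomplexes <- function(xf, fs, cfg = kc_config(),
                              segment_id = 1L) {
  stopifnot(inherits(cfg, "kc_config"))
  xf <- as.numeric(xf)
  n <- length(xf)
  if (n < 3L) return(sw_events())
  mins <- local_minima_1d(xf)
  mins <- mins[mins$value <= cfg$threshold, , drop = FALSE]
  if (nrow(mins) == 0L) return(sw_events())

  # resolve close pairs: deepest-first greedy keep
  ord <- order(mins$value)
  sep <- cfg$min_separation_s * fs
  kept <- integer(0)
  for (k in ord) {
    if (all(abs(mins$index[k] - mins$index[kept]) >= sep)) {
      kept <- c(kept, k)
    }
  }
  mins <- mins[sort(kept), , drop = FALSE]

  half_floor <- ceiling(cfg$min_duration_s / 2 * fs)
  ev <- lapply(seq_len(nrow(mins)), function(k) {
    ti <- mins$index[k]
    # walk left to the last non-negative sample before the trough
    lo <- ti
    while (lo > 1L && xf[lo] < 0) lo <- lo - 1L
    if (xf[lo] < 0) lo <- NA_integer_
    # positive peak after the trough, then its closing zero-crossing
    hi <- NA_integer_
    j <- ti
    while (j < n && xf[j] < 0) j <- j + 1L          # rising zero-crossing
    if (j < n && xf[j] >= 0) {
      while (j < n && xf[j + 1L] >= xf[j]) j <- j + 1L   # climb to the peak
      while (j < n && xf[j] > 0) j <- j + 1L             # fall back to zero
      hi <- j
    }
    fb <- round(0.75 * fs)
    if (is.na(lo)) lo <- max(1L, ti - fb)
    if (is.na(hi)) hi <- min(n, ti + fb)
    # enforce the duration floor symmetrically around the trough
    if (lo > ti - half_floor) lo <- max(1L, ti - half_floor)
    if (hi < ti + half_floor) hi <- min(n, ti + half_floor)
    c(lo, hi, mins$value[k], ti)
  })
  m <- do.call(rbind, ev)

  # events are anchored at troughs >= sep apart, but extents could still
  # bring onsets closer; drop the shallower of any violating pair
  if (nrow(m) > 1L) {
    keep <- rep(TRUE, nrow(m))
    for (k in 2L:nrow(m)) {
      prev <- max(which(keep[seq_len(k - 1L)]))
      if (m[k, 1L] - m[prev, 1L] < sep) {
        if (m[k, 3L] < m[prev, 3L]) keep[prev] <- FALSE else keep[k] <- FALSE
      }
    }
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) == 0L) return(sw_events())
  sw_events(kind = "kcomplex", segment_id = segment_id,
            start_s = (m[, 1L] - 1) / fs, end_s = m[, 2L] / fs,
            peak_value = m[, 3L], peak_time_s = (m[, 4L] - 1) / fs)
}
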