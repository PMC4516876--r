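# Sleep spindle detection.
#
# The oscillatory component of the decomposition is mapped into the
# 11-16 Hz band with a continuous wavelet transform built on complex
# frequency B-spline (fbsp) wavelets,
#
#   psi(t) = fb * sinc^m(t * fb / m) * exp(i 2 pi fc t),
#
# candidate spindles are the strict 8-neighbour local maxima of the
# squared-magnitude time-frequency map, and a trained amplitude threshold
# (in microvolt^2) decides which maxima become events.

#' Complex frequency B-spline wavelet
#'
#' Evaluates `fb * sinc^m(t * fb / m) * exp(i 2 pi fc t)` with
#' `sinc(x) = sin(pi x) / (pi x)` and `sinc(0) = 1`.
#'
#' @param t numeric vector of times (in the wavelet's natural unit).
#' @param m integer order `>= 1`; larger m gives a smoother, more
#'   oscillatory envelope (m = 25 throughout this package).
#' @param fb bandwidth parameter (> 0).
#' @param fc centre frequency parameter (> 0).
#' @return Complex vector, `length(t)`.
#' @export
fbsp_wavelet <- function(t, m = 25L, fb = 1, fc = 1) {
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    stop("`m` must be an integer >= 1", call. = FALSE)
  }
  if (fb <= 0 || fc <= 0) stop("`fb` and `fc` must be > 0", call. = FALSE)
  x <- t * fb / m
  s <- ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  fb * s^m * exp(2i * pi * fc * t)
}

## half-width of the fbsp support in natural time units: the envelope
## sinc^m(u/m) ~ exp(-pi^2 u^2 / (6 m)) has effective std sqrt(3m)/pi
fbsp_halfwidth <- function(m) ceiling(4 * sqrt(3 * m) / pi)

#' CWT time-frequency map of the spindle band
#'
#' Computes the squared magnitude of the continuous wavelet transform of a
#' signal on a grid of analysis frequencies inside the spindle band,
#' using the fbsp wavelet. Scales map to frequency through the
#' pseudo-frequency relation `f = fc * fs / scale`.
#'
#' @param x oscillatory component, numeric vector in microvolts.
#' @param fs sampling rate in Hz (> 32).
#' @param freqs analysis frequencies in Hz, all inside `[11, 16]`
#'   (default 11 to 16 in 0.25 Hz steps).
#' @param m,fb,fc fbsp wavelet parameters, see [fbsp_wavelet()].
#' @param segment_id optional segment label carried in the result.
#' @return Object of class `sw_tfmap`: list with `values` (matrix,
#'   frequencies x time, microvolt^2), `freqs` (Hz), `times` (s), `fs`,
#'   `segment_id`.
#' @export
cwt_tfmap <- function(x, fs, freqs = seq(11, 16, by = 0.25),
                      m = 25L, fb = 1, fc = 1, segment_id = NA_integer_) {
  if (fs <= 32) stop("`fs` must exceed 32 Hz", call. = FALSE)
  if (any(freqs < 11 - 1e-9) || any(freqs > 16 + 1e-9)) {
    stop("analysis frequencies must lie in the 11-16 Hz spindle band",
         call. = FALSE)
  }
  if (length(x) < 8L) stop("signal too short", call. = FALSE)
  x <- as.numeric(x)
  n <- length(x)
  vals <- matrix(0, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    a <- fc * fs / freqs[i]                 # scale in samples
    L <- ceiling(fbsp_halfwidth(m) * a)
    u <- (-L:L) / a
    kern <- Conj(fbsp_wavelet(u, m = m, fb = fb, fc = fc))
    # L1 normalization: a unit-amplitude tone at the analysis frequency
    # maps to |W| ~ 1/2, i.e. the map reads in amplitude^2 (microvolt^2)
    kern <- kern / sum(Mod(kern))
    # W[b] = sum_j x[b + j] * kern[j], via FFT convolution
    vals[i, ] <- Mod(fft_xcorr(x, kern, L))^2
  }
  structure(list(values = vals, freqs = freqs,
                 times = (seq_len(n) - 1) / fs, fs = fs,
                 wavelet_m = m, segment_id = segment_id),
            class = "sw_tfmap")
}

## cross-correlation of x with a centred kernel k (indices -L..L),
## zero-padded edges, FFT-accelerated; returns length(x) values
fft_xcorr <- function(x, k, L) {
  n <- length(x)
  nk <- length(k)
  nf <- stats::nextn(n + nk - 1L, 2)
  xf <- stats::fft(c(x, rep(0, nf - n)))
  # conv(x, rev(k))[b + L] = sum_j x[b + j] k[j]
  kf <- stats::fft(c(rev(k), rep(0+0i, nf - nk)))
  full <- stats::fft(xf * kf, inverse = TRUE) / nf
  full[(L + 1L):(L + n)]
}

#' Strict 8-neighbour local maxima of a time-frequency map
#'
#' A point is a local maximum when its value strictly exceeds all eight
#' surrounding neighbours. Border rows and columns are excluded (all
#' eight neighbours must exist); plateaus produce no maxima.
#'
#' @param map an `sw_tfmap`, or a plain numeric matrix (frequencies x
#'   time) with at least 3 rows and 3 columns.
#' @return `data.frame` with `freq_idx`, `time_idx`, `value`, sorted by
#'   decreasing value.
#' @export
local_maxima_2d <- function(map) {
  v <- if (inherits(map, "sw_tfmap")) map$values else map
  if (!is.matrix(v) || nrow(v) < 3L || ncol(v) < 3L) {
    stop("map must have at least 3 rows and 3 columns", call. = FALSE)
  }
  nr <- nrow(v); nc <- ncol(v)
  ri <- 2L:(nr - 1L); ci <- 2L:(nc - 1L)
  cen <- v[ri, ci, drop = FALSE]
  ismax <- cen > v[ri - 1L, ci - 1L, drop = FALSE] &
    cen > v[ri - 1L, ci, drop = FALSE] &
    cen > v[ri - 1L, ci + 1L, drop = FALSE] &
    cen > v[ri, ci - 1L, drop = FALSE] &
    cen > v[ri, ci + 1L, drop = FALSE] &
    cen > v[ri + 1L, ci - 1L, drop = FALSE] &
    cen > v[ri + 1L, ci, drop = FALSE] &
    cen > v[ri + 1L, ci + 1L, drop = FALSE]
  idx <- which(ismax, arr.ind = TRUE)
  out <- data.frame(freq_idx = idx[, 1L] + 1L, time_idx = idx[, 2L] + 1L,
                    value = cen[ismax])
  out[order(-out$value), , drop = FALSE]
}

#' Candidate spindle events of a time-frequency map
#'
#' Builds the threshold-independent event partition of a map: around
#' every strict 8-neighbour local maximum (above a small structural floor,
#' `floor_frac` of the map's global maximum, which keeps meaninglessly
#' wide extents of noise-level maxima out of the partition) the extent is
#' the maximal contiguous run of time points whose across-frequency
#' maximum stays above `extent_frac` of that maximum; overlapping
#' extents, or extents separated by less than `merge_gap_s`, are merged.
#' Each candidate carries its largest triggering maximum as `peak_value`,
#' so thresholding reduces to a filter on `peak_value` and the detected
#' event count is non-increasing in the threshold by construction.
#'
#' The default `extent_frac = 0.25` on the squared-magnitude map is a 50%
#' amplitude (-6 dB) drop, the customary definition of a spindle's
#' visible extent. Because the analysing wavelet itself spreads any
#' feature by its own envelope width `sigma_w = sqrt(3 m) / (pi f)`
#' seconds, the AASM duration floor is applied to a deconvolved duration
#' estimate: treating burst and wavelet envelopes as Gaussians whose
#' widths add in quadrature, a burst whose visible duration is `6 sigma`
#' has half-amplitude extent `2.355 * sqrt(sigma^2 + sigma_w^2)`, so
#' `dur_est = 6 * sqrt(max((extent / 2.355)^2 - sigma_w^2, 0))` and the
#' candidate is kept when `dur_est >= min_duration_s`.
#'
#' @param map an `sw_tfmap` from [cwt_tfmap()].
#' @param min_duration_s minimum (deconvolved) event duration (default
#'   0.5 s, the AASM floor).
#' @param max_duration_s optional maximum duration; `NULL` (default)
#'   means no cap.
#' @param extent_frac relative drop (on the power map) defining the event
#'   extent (default 0.25, i.e. half the peak amplitude).
#' @param merge_gap_s extents separated by less than this gap are merged
#'   (default 0.25 s).
#' @param floor_frac structural floor for partition-building maxima, as a
#'   fraction of the global map maximum (default 0.05).
#' @return An [sw_events()] table of candidate spindles (all thresholds).
#' @export
spindle_candidates <- function(map, min_duration_s = 0.5,
                               max_duration_s = NULL, extent_frac = 0.25,
                               merge_gap_s = 0.25, floor_frac = 0.05) {
  stopifnot(inherits(map, "sw_tfmap"))
  mx <- local_maxima_2d(map)
  mx <- mx[mx$value >= floor_frac * max(map$values), , drop = FALSE]
  if (nrow(mx) == 0L) return(sw_events())
  colmax <- apply(map$values, 2L, max)
  fs <- map$fs
  n <- ncol(map$values)

  iv <- lapply(seq_len(nrow(mx)), function(k) {
    ti <- mx$time_idx[k]
    lev <- extent_frac * mx$value[k]
    lo <- ti
    while (lo > 1L && colmax[lo - 1L] >= lev) lo <- lo - 1L
    hi <- ti
    while (hi < n && colmax[hi + 1L] >= lev) hi <- hi + 1L
    c(lo, hi, mx$value[k], ti, mx$freq_idx[k])
  })
  iv <- do.call(rbind, iv)
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]

  # merge overlapping or nearly-adjacent extents
  gap <- merge_gap_s * fs
  merged <- list()
  cur <- iv[1L, ]
  for (k in seq_len(nrow(iv))[-1L]) {
    if (iv[k, 1L] <= cur[2L] + gap) {
      cur[2L] <- max(cur[2L], iv[k, 2L])
      if (iv[k, 3L] > cur[3L]) {
        cur[3L] <- iv[k, 3L]; cur[4L] <- iv[k, 4L]; cur[5L] <- iv[k, 5L]
      }
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- iv[k, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  m <- do.call(rbind, merged)

  start_s <- (m[, 1L] - 1) / fs
  end_s <- m[, 2L] / fs           # half-open: last sample + one period
  # deconvolve the wavelet's own envelope width from the -6 dB extent
  fwhm <- 2 * sqrt(2 * log(2))    # 2.3548: half-amplitude width of a Gaussian
  sigma_w <- sqrt(3 * map$wavelet_m) / pi / map$freqs[m[, 5L]]
  dur_est <- 6 * sqrt(pmax(((end_s - start_s) / fwhm)^2 - sigma_w^2, 0))
  keep <- dur_est >= min_duration_s
  if (!is.null(max_duration_s)) keep <- keep & dur_est <= max_duration_s
  if (!any(keep)) return(sw_events())
  sw_events(kind = "spindle",
            segment_id = if (is.na(map$segment_id)) 1L else map$segment_id,
            start_s = start_s[keep], end_s = end_s[keep],
            peak_value = m[keep, 3L], peak_time_s = (m[keep, 4L] - 1) / fs)
}

#' Detect sleep spindles on a time-frequency map
#'
#' Applies an amplitude threshold (microvolt^2) to the candidate events
#' of [spindle_candidates()]: a candidate is detected when its triggering
#' local maximum exceeds `threshold`.
#'
#' @inheritParams spindle_candidates
#' @param threshold detection threshold in microvolt^2 (>= 0).
#' @param candidates optionally, a precomputed [spindle_candidates()]
#'   table for this map (used to sweep thresholds cheaply).
#' @return An [sw_events()] table of spindles.
#' @export
detect_spindles <- function(map, threshold, min_duration_s = 0.5,
                            max_duration_s = NULL, extent_frac = 0.25,
                            merge_gap_s = 0.25, candidates = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    stop("`threshold` must be >= 0", call. = FALSE)
  }
  if (is.null(candidates)) {
    candidates <- spindle_candidates(map, min_duration_s, max_duration_s,
                                     extent_frac, merge_gap_s)
  }
  candidates[candidates$peak_value > threshold, , drop = FALSE]
}

#' Rank candidate wavelets by cross-correlation with spindle waveforms
#'
#' For each waveform snippet and each candidate mother wavelet, computes
#' the peak of the normalized cross-correlation between the snippet and
#' the real part of the wavelet rendered at `freq` Hz, and summarizes per
#' wavelet. Used to justify the fbsp choice for the spindle CWT.
#'
#' @param waveforms list of numeric vectors (spindle-band snippets,
#'   each at least 0.5 s long).
#' @param fs sampling rate in Hz.
#' @param freq rendering frequency for the candidates (default 13 Hz).
#' @param wavelets character vector of candidates among `"fbsp"`,
#'   `"cmor"`, `"shan"`, `"gauss"`.
#' @return List with `correlations` (matrix snippets x wavelets, values in
#'   `[0, 1]`) and `summary` (data.frame: wavelet, median, max).
#' @export
waveform_crosscorr <- function(waveforms, fs, freq = 13,
                               wavelets = c("fbsp", "cmor", "shan", "gauss")) {
  if (!is.list(waveforms) || length(waveforms) == 0L) {
    stop("`waveforms` must be a non-empty list of numeric vectors",
         call. = FALSE)
  }
  if (any(vapply(waveforms, length, 1L) < 0.5 * fs)) {
    stop("each snippet must be at least 0.5 s long", call. = FALSE)
  }
  render <- function(name) {
    # ~1 s of support at the rendering frequency
    tt <- seq(-0.6, 0.6, by = 1 / fs)
    switch(name,
      fbsp = Re(fbsp_wavelet(tt * freq, m = 25L)),
      cmor = exp(-(tt * freq)^2 / 2) * cos(2 * pi * freq * tt),
      shan = Re(fbsp_wavelet(tt * freq, m = 1L)),
      gauss = {
        # second derivative of a Gaussian (real-valued, ~1.5 lobes)
        s <- 1 / (2 * freq)
        (1 - (tt / s)^2) * exp(-(tt / s)^2 / 2)
      },
      stop(sprintf("unknown wavelet '%s'", name), call. = FALSE))
  }
  cors <- sapply(wavelets, function(wn) {
    wv <- render(wn)
    wv <- wv / sqrt(sum(wv^2))
    vapply(waveforms, function(s) {
      s <- as.numeric(s)
      cc <- fft_xcorr(s, wv, (length(wv) - 1L) %/% 2L)
      denom <- sqrt(sum(s^2))
      if (denom == 0) return(0)
      min(max(Mod(cc)) / denom, 1)
    }, numeric(1))
  })
  cors <- matrix(cors, nrow = length(waveforms),
                 dimnames = list(NULL, wavelets))
  list(correlations = cors,
       summary = data.frame(wavelet = wavelets,
                            median = apply(cors, 2L, stats::median),
                            max = apply(cors, 2L, max),
                            row.names = NULL))
}
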