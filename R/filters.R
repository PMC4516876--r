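# Zero-phase FIR band-pass filtering (windowed-sinc design).
#
# All band-pass steps in the pipeline (0.2-40 Hz artifact filter, 0.5-5 Hz
# K-complex filter, 12-15 Hz RMS baseline filter) use the same design: a
# Hamming-windowed sinc difference, applied as a single centred
# convolution. The kernel is symmetric (linear phase type I), so centred
# application is exactly zero-phase and preserves trough timing. Each
# low-pass prototype is normalized to unit DC gain before differencing,
# which makes the band-pass DC gain exactly zero.

#' Design a windowed-sinc band-pass FIR kernel
#'
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param n_taps odd kernel length; `NULL` (default) picks
#'   `3.3 * fs / min(low, (high - low)/2)`, enough for the narrower of the
#'   lower transition and half the bandwidth.
#' @return Numeric vector of odd length (the symmetric impulse response).
#' @export
fir_bandpass_design <- function(fs, low, high, n_taps = NULL) {
  if (low <= 0 || high <= low) stop("need 0 < low < high", call. = FALSE)
  if (fs <= 2 * high) {
    stop(sprintf("sampling rate %g Hz too low for a %g Hz band edge", fs, high),
         call. = FALSE)
  }
  if (is.null(n_taps)) {
    n_taps <- ceiling(3.3 * fs / min(low, (high - low) / 2))
  }
  n_taps <- as.integer(n_taps)
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  M <- (n_taps - 1L) / 2L
  k <- -M:M
  win <- 0.54 + 0.46 * cos(pi * k / M)  # Hamming
  lp <- function(fc) {
    h <- ifelse(k == 0, 2 * fc / fs, sin(2 * pi * fc * k / fs) / (pi * k)) * win
    h / sum(h)  # unit DC gain -> exact zero DC for the difference
  }
  lp(high) - lp(low)
}

#' Zero-phase filtering with a symmetric FIR kernel
#'
#' Convolves the signal with a centred symmetric kernel (zero phase).
#' Edges are mirror-extended before filtering, which suppresses the step
#' transients that zero padding would create; output length equals input
#' length.
#'
#' @param x numeric signal.
#' @param kernel symmetric impulse response of odd length.
#' @return Filtered signal, `length(x)`.
#' @export
fir_filter <- function(x, kernel) {
  n <- length(x)
  nk <- length(kernel)
  if (nk %% 2L == 0L) stop("kernel length must be odd", call. = FALSE)
  L <- (nk - 1L) %/% 2L
  if (n < 2L) return(x * sum(kernel))
  Lp <- min(L, n - 1L)
  xp <- if (Lp > 0L) c(x[(Lp + 1L):2L], x, x[(n - 1L):(n - Lp)]) else x
  Re(fft_xcorr(xp, kernel, L))[(Lp + 1L):(Lp + n)]
}

#' Band-pass filter a signal between two edge frequencies
#'
#' Convenience wrapper: design with [fir_bandpass_design()] and apply with
#' [fir_filter()].
#'
#' @inheritParams fir_bandpass_design
#' @param x numeric signal in microvolts.
#' @return Filtered signal, same length.
#' @export
bandpass <- function(x, fs, low, high, n_taps = NULL) {
  fir_filter(as.numeric(x), fir_bandpass_design(fs, low, high, n_taps))
}
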