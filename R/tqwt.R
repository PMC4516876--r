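# Tunable Q-factor wavelet transform (TQWT).
#
# An oversampled two-channel filter bank iterated on its low-pass branch.
# The oscillatory character of the wavelet is set by the Q-factor and the
# overcompleteness by the redundancy r; both map onto two frequency-domain
# scaling factors,
#
#   beta = 2 / (Q + 1),     alpha = 1 - beta / r,
#
# with 0 < alpha < 1 and 0 < beta <= 1.  Perfect reconstruction requires
# alpha + beta > 1.  The filters are specified directly in the DFT domain
# with a Daubechies-type transition function
#
#   theta(w) = 0.5 * (1 + cos w) * sqrt(2 - cos w),   |w| <= pi,
#
# which satisfies theta(w)^2 + theta(pi - w)^2 = 1 so that the analysis /
# synthesis pair is a Parseval frame: the inverse transform is the adjoint
# and reconstruction is exact to round-off.

#' TQWT parameter set
#'
#' Builds and validates the parameter triple (Q, r, J) of a tunable
#' Q-factor wavelet transform together with the derived filter scaling
#' factors `alpha` (low-pass) and `beta` (high-pass).
#'
#' @param Q Q-factor, dimensionless, > 0. High Q yields oscillatory
#'   wavelets (many cycles), Q = 1 yields transient-like wavelets.
#' @param r redundancy (oversampling rate) of the transform, > 1. `r = 3`
#'   is the customary choice for biomedical signals.
#' @param J number of decomposition levels (>= 1), or `NULL` to defer the
#'   choice to [tqwt_max_levels()] at transform time.
#' @param N optional signal length the parameters will be applied to; when
#'   given, `J` (or its default `J_max`) is validated against it.
#'
#' @return An object of class `tqwt_params`: a list with elements `Q`,
#'   `r`, `J`, `alpha`, `beta`.
#' @examples
#' p <- tqwt_params(Q = 5.5, r = 3, N = 6000)
#' p$alpha; p$beta; p$J
#' @export
tqwt_params <- function(Q, r, J = NULL, N = NULL) {
  sc <- compute_filter_scalings(Q, r)
  if (!is.null(J)) {
    if (!is.numeric(J) || length(J) != 1L || !is.finite(J) || J < 1 ||
        J != round(J)) {
      stop("`J` must be a positive integer", call. = FALSE)
    }
    J <- as.integer(J)
  }
  if (!is.null(N)) {
    Jmax <- tqwt_max_levels(N, sc[["alpha"]], sc[["beta"]])
    if (is.null(J)) J <- Jmax
    if (J > Jmax) {
      stop(sprintf("J = %d exceeds J_max = %d for N = %d", J, Jmax, N),
           call. = FALSE)
    }
  }
  structure(list(Q = Q, r = r, J = J,
                 alpha = sc[["alpha"]], beta = sc[["beta"]]),
            class = "tqwt_params")
}

#' @export
print.tqwt_params <- function(x, ...) {
  cat(sprintf("TQWT parameters: Q = %g, r = %g, J = %s (alpha = %.6f, beta = %.6f)\n",
              x$Q, x$r, if (is.null(x$J)) "auto" else x$J, x$alpha, x$beta))
  invisible(x)
}

#' Filter scaling factors from (Q, r)
#'
#' Inverts the defining relations Q = (2 - beta)/beta and r = beta/(1 - alpha)
#' to obtain the low-pass scaling `alpha` and high-pass scaling `beta`.
#'
#' @inheritParams tqwt_params
#' @return Named numeric vector `c(alpha = , beta = )`.
#' @export
compute_filter_scalings <- function(Q, r) {
  if (!is.numeric(Q) || length(Q) != 1L || !is.finite(Q) || Q <= 0) {
    stop("`Q` must be a finite scalar > 0", call. = FALSE)
  }
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 1) {
    stop("`r` must be a finite scalar > 1", call. = FALSE)
  }
  beta <- 2 / (Q + 1)
  alpha <- 1 - beta / r
  # r > 1 guarantees the oversampling condition alpha + beta > 1
  stopifnot(alpha > 0, alpha < 1, beta > 0, beta <= 1, alpha + beta > 1)
  c(alpha = alpha, beta = beta)
}

#' Maximum number of decomposition levels
#'
#' `J_max = floor( log(beta * N / 8) / log(1 / alpha) )`. Deeper levels
#' would produce subbands shorter than the filters' transition bands.
#'
#' @param N signal length in samples (>= 16).
#' @param alpha,beta filter scaling factors, see [compute_filter_scalings()].
#' @return Integer `J_max >= 1`.
#' @export
tqwt_max_levels <- function(N, alpha, beta) {
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N < 16) {
    stop("`N` must be a scalar >= 16", call. = FALSE)
  }
  if (beta * N / 8 <= 1) {
    stop(sprintf("signal too short for these filters: beta*N/8 = %.3f <= 1",
                 beta * N / 8), call. = FALSE)
  }
  J <- floor(log(beta * N / 8) / log(1 / alpha))
  as.integer(max(J, 0L))
}

## Daubechies-type transition function; theta(0)=1, theta(pi)=0,
## theta(w)^2 + theta(pi-w)^2 = 1.
tqwt_theta <- function(w) 0.5 * (1 + cos(w)) * sqrt(2 - cos(w))

## Subband lengths used at each level for padded input length N:
##   N0_j = 2*round(alpha^j   * N / 2)   (low-pass chain)
##   N1_j = 2*round(beta*alpha^(j-1) * N / 2)   (high-pass subband j)
tqwt_subband_lengths <- function(N, alpha, beta, J) {
  list(n0 = 2 * round(alpha^(seq_len(J)) * N / 2),
       n1 = 2 * round(beta * alpha^(seq_len(J) - 1) * N / 2))
}

## Smallest even padded length >= N for which every level of the filter
## bank is realizable (non-negative pass/transition/stop band sizes and
## subbands of length >= 4).
tqwt_padded_length <- function(N, alpha, beta, J) {
  Np <- as.integer(2 * ceiling(N / 2))
  repeat {
    ln <- tqwt_subband_lengths(Np, alpha, beta, J)
    prev <- c(Np, ln$n0[-J])
    ok <- all(ln$n0 >= 4) && all(ln$n1 >= 4) &&
      all(ln$n0 + ln$n1 - prev >= 2) &&   # transition band T >= 0
      all(ln$n1 <= prev) && all(ln$n0 <= prev)
    if (ok) return(Np)
    Np <- Np + 2L
    if (Np > 16L * N + 64L) {
      stop("cannot find a realizable padded length; J too large for N",
           call. = FALSE)
    }
  }
}

## Unitary DFT pair
udft <- function(x) stats::fft(x) / sqrt(length(x))
uidft <- function(X) stats::fft(X, inverse = TRUE) / sqrt(length(X))

## One analysis filter-bank stage in the DFT domain.
## X: uDFT of current low-pass signal (even length n); returns list(V0, V1)
## of lengths n0 (low-pass) and n1 (high-pass).
tqwt_afb <- function(X, n0, n1) {
  n <- length(X)
  p <- (n - n1) / 2L            # pass-band size
  tb <- (n0 + n1 - n) / 2L - 1L # transition-band size
  stopifnot(p >= 0, tb >= -1, (n - n0) / 2 >= 0)
  trans <- if (tb > 0) tqwt_theta(seq_len(tb) * pi / (tb + 1)) else numeric(0)

  V0 <- complex(n0)
  V0[1L] <- X[1L]
  if (p > 0) V0[2L:(p + 1L)] <- X[2L:(p + 1L)]
  if (tb > 0) {
    V0[(p + 2L):(p + tb + 1L)] <- X[(p + 2L):(p + tb + 1L)] * trans
    V0[(n0 - p - tb + 1L):(n0 - p)] <- X[(n - p - tb + 1L):(n - p)] * rev(trans)
  }
  V0[n0 / 2L + 1L] <- 0
  if (p > 0) V0[(n0 - p + 1L):n0] <- X[(n - p + 1L):n]

  V1 <- complex(n1)
  if (tb > 0) {
    V1[2L:(tb + 1L)] <- X[(p + 2L):(p + tb + 1L)] * rev(trans)
    V1[(n1 - tb + 1L):n1] <- X[(n - p - tb + 1L):(n - p)] * trans
  }
  if (n1 / 2L >= tb + 2L) V1[(tb + 2L):(n1 / 2L)] <- X[(p + tb + 2L):(n / 2L)]
  V1[n1 / 2L + 1L] <- X[n / 2L + 1L]
  if (n1 - tb >= n1 / 2L + 2L) {
    V1[(n1 / 2L + 2L):(n1 - tb)] <- X[(n / 2L + 2L):(n - p - tb)]
  }
  list(V0 = V0, V1 = V1)
}

## One synthesis stage (adjoint of tqwt_afb): combine V0 (n0) and V1 (n1)
## into the uDFT of the parent signal of length n.
tqwt_sfb <- function(V0, V1, n) {
  n0 <- length(V0); n1 <- length(V1)
  p <- (n - n1) / 2L
  tb <- (n0 + n1 - n) / 2L - 1L
  trans <- if (tb > 0) tqwt_theta(seq_len(tb) * pi / (tb + 1)) else numeric(0)

  Y <- complex(n)
  Y[1L] <- V0[1L]
  if (p > 0) {
    Y[2L:(p + 1L)] <- V0[2L:(p + 1L)]
    Y[(n - p + 1L):n] <- V0[(n0 - p + 1L):n0]
  }
  if (tb > 0) {
    Y[(p + 2L):(p + tb + 1L)] <-
      V0[(p + 2L):(p + tb + 1L)] * trans + V1[2L:(tb + 1L)] * rev(trans)
    Y[(n - p - tb + 1L):(n - p)] <-
      V0[(n0 - p - tb + 1L):(n0 - p)] * rev(trans) + V1[(n1 - tb + 1L):n1] * trans
  }
  if (n / 2L >= p + tb + 2L) Y[(p + tb + 2L):(n / 2L)] <- V1[(tb + 2L):(n1 / 2L)]
  Y[n / 2L + 1L] <- V1[n1 / 2L + 1L]
  if (n - p - tb >= n / 2L + 2L) {
    Y[(n / 2L + 2L):(n - p - tb)] <- V1[(n1 / 2L + 2L):(n1 - tb)]
  }
  Y
}

#' Forward tunable Q-factor wavelet transform
#'
#' Decomposes a real signal into `J` high-pass subbands plus one final
#' low-pass subband by iterating the TQWT two-channel filter bank on the
#' low-pass branch. The input is zero-padded to the smallest even length
#' for which every stage is realizable; [tqwt_inverse()] truncates back.
#'
#' @param x real numeric vector (signal samples, conventionally microvolts).
#' @param params a [tqwt_params()] object. A `NULL` `J` defaults to
#'   `J_max` for the (padded) signal length.
#' @return An object of class `tqwt_subbands`: list with `highpass` (list
#'   of `J` numeric vectors, level 1 = highest frequency band), `lowpass`
#'   (final low-pass vector), `params`, `input_length`, `padded_length`.
#' @seealso [tqwt_inverse()]
#' @examples
#' x <- sin(2 * pi * 13 * (0:999) / 200)
#' w <- tqwt_forward(x, tqwt_params(Q = 5.5, r = 3, N = 1000))
#' length(w$highpass)
#' max(abs(tqwt_inverse(w) - x))
#' @export
tqwt_forward <- function(x, params) {
  stopifnot(inherits(params, "tqwt_params"))
  if (length(x) == 0L) stop("empty signal", call. = FALSE)
  if (!is.numeric(x) || !all(is.finite(x))) {
    stop("signal must be finite numeric", call. = FALSE)
  }
  N <- length(x)
  alpha <- params$alpha; beta <- params$beta
  J <- params$J
  if (is.null(J)) J <- tqwt_max_levels(N, alpha, beta)
  Jmax <- tqwt_max_levels(N, alpha, beta)
  if (J > Jmax) {
    stop(sprintf("J = %d exceeds J_max = %d for signal length %d", J, Jmax, N),
         call. = FALSE)
  }
  Np <- tqwt_padded_length(N, alpha, beta, J)
  xp <- c(as.numeric(x), numeric(Np - N))
  ln <- tqwt_subband_lengths(Np, alpha, beta, J)

  sb <- .tqwt_fwd_cpp(xp, as.integer(ln$n0), as.integer(ln$n1))
  highpass <- sb[seq_len(J)]
  lowpass <- sb[[J + 1L]]
  structure(list(highpass = highpass, lowpass = lowpass,
                 params = tqwt_params(params$Q, params$r, J),
                 input_length = N, padded_length = Np),
            class = "tqwt_subbands")
}

#' @export
print.tqwt_subbands <- function(x, ...) {
  cat(sprintf("TQWT subbands: J = %d high-pass + 1 low-pass, input length %d\n",
              length(x$highpass), x$input_length))
  cat("  lengths:", paste(c(vapply(x$highpass, length, 1L), length(x$lowpass)),
                          collapse = " "), "\n")
  invisible(x)
}

#' Inverse tunable Q-factor wavelet transform
#'
#' Exact (Parseval-frame adjoint) reconstruction from a subband set
#' produced by [tqwt_forward()], or from one with modified coefficients.
#'
#' @param w a `tqwt_subbands` object.
#' @return Numeric vector of length `w$input_length`.
#' @export
tqwt_inverse <- function(w) {
  stopifnot(inherits(w, "tqwt_subbands"))
  J <- length(w$highpass)
  Np <- w$padded_length
  ln <- tqwt_subband_lengths(Np, w$params$alpha, w$params$beta, J)
  if (length(w$lowpass) != ln$n0[J] ||
      !all(vapply(w$highpass, length, 1L) == ln$n1)) {
    stop("inconsistent subband lengths for the stored parameters",
         call. = FALSE)
  }
  xp <- .tqwt_inv_cpp(c(w$highpass, list(w$lowpass)), as.integer(Np),
                      as.integer(ln$n0), as.integer(ln$n1))
  as.numeric(xp)[seq_len(w$input_length)]
}

## Pure-R reference implementations of the cascade (used as an independent
## oracle against the compiled path in the test suite).
tqwt_forward_ref <- function(xp, n0s, n1s) {
  X <- udft(xp)
  J <- length(n0s)
  out <- vector("list", J + 1L)
  for (j in seq_len(J)) {
    fb <- tqwt_afb(X, n0s[j], n1s[j])
    out[[j]] <- Re(uidft(fb$V1))
    X <- fb$V0
  }
  out[[J + 1L]] <- Re(uidft(X))
  out
}

tqwt_inverse_ref <- function(subbands, np, n0s, n1s) {
  J <- length(n0s)
  Y <- udft(subbands[[J + 1L]])
  for (j in rev(seq_len(J))) {
    n_parent <- if (j == 1L) np else n0s[j - 1L]
    Y <- tqwt_sfb(Y, udft(subbands[[j]]), n_parent)
  }
  Re(uidft(Y))
}

#' Equivalent frequency responses of the level-j filter bank
#'
#' Samples the cascade frequency responses of the level-`j` low-pass and
#' high-pass branches on a uniform grid of `grid_size` angular frequencies
#' in `[-pi, pi]`. The low-pass cascade is
#' `prod_{m=0}^{j-1} H0(w / alpha^m)` supported on `|w| <= alpha^j * pi`;
#' the high-pass branch response is
#' `H1(w / alpha^(j-1)) * prod_{m=0}^{j-2} H0(w / alpha^m)` supported on
#' `(1-beta) * alpha^(j-1) * pi <= |w| <= alpha^(j-1) * pi`.
#'
#' @param params a [tqwt_params()] object with non-`NULL` `J`.
#' @param level level `j`, `1 <= j <= params$J`.
#' @param grid_size number of grid points (default 1024).
#' @return List with `omega`, `h0`, `h1` (numeric vectors) and `level`.
#' @export
tqwt_filter_response <- function(params, level, grid_size = 1024L) {
  stopifnot(inherits(params, "tqwt_params"))
  J <- params$J
  if (is.null(J)) stop("`params$J` must be set", call. = FALSE)
  if (!is.numeric(level) || length(level) != 1L || level < 1 || level > J ||
      level != round(level)) {
    stop(sprintf("`level` must be an integer in [1, %d]", J), call. = FALSE)
  }
  alpha <- params$alpha; beta <- params$beta
  omega <- seq(-pi, pi, length.out = grid_size)

  h0_base <- function(w) {
    a <- abs(w)
    out <- numeric(length(w))
    out[a <= (1 - beta) * pi] <- 1
    tr <- a > (1 - beta) * pi & a < alpha * pi
    out[tr] <- tqwt_theta((a[tr] + (beta - 1) * pi) / (alpha + beta - 1))
    out
  }
  h1_base <- function(w) {
    a <- abs(w)
    out <- numeric(length(w))
    out[a >= alpha * pi & a <= pi] <- 1
    tr <- a > (1 - beta) * pi & a < alpha * pi
    out[tr] <- tqwt_theta((alpha * pi - a[tr]) / (alpha + beta - 1))
    out
  }

  j <- as.integer(level)
  h0 <- rep(1, grid_size)
  for (m in seq_len(j) - 1L) h0 <- h0 * h0_base(omega / alpha^m)
  h1 <- h1_base(omega / alpha^(j - 1L))
  if (j >= 2L) for (m in seq_len(j - 1L) - 1L) h1 <- h1 * h0_base(omega / alpha^m)
  # base responses are only defined on [-pi, pi]; the cascade argument
  # w / alpha^m exceeds pi outside the stated supports, where the response
  # is zero by construction
  h0[abs(omega) > alpha^j * pi] <- 0
  h1[abs(omega) > alpha^(j - 1L) * pi | abs(omega) < (1 - beta) * alpha^(j - 1L) * pi] <- 0
  list(omega = omega, h0 = h0, h1 = h1, level = j)
}

#' Synthesis wavelet of one subband
#'
#' Returns the time-domain waveform obtained by inverting a unit impulse
#' placed at the centre of subband `j` (1..J for high-pass, J+1 for the
#' final low-pass), for a transform applied to signals of length `N`.
#' Used for wavelet-norm based regularization weights and for wavelet
#' shape inspection.
#'
#' @param params a [tqwt_params()] object.
#' @param j subband index in `1..(J+1)`.
#' @param N signal length the transform is applied to.
#' @return Numeric vector of length `N`.
#' @export
tqwt_synthesis_wavelet <- function(params, j, N) {
  w <- tqwt_forward(numeric(N), params)
  J <- length(w$highpass)
  if (j < 1 || j > J + 1) stop("subband index out of range", call. = FALSE)
  if (j <= J) {
    w$highpass[[j]][ceiling(length(w$highpass[[j]]) / 2)] <- 1
  } else {
    w$lowpass[ceiling(length(w$lowpass) / 2)] <- 1
  }
  tqwt_inverse(w)
}
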