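# Morphological component analysis with dual TQWT dictionaries.
#
# An EEG segment x is modelled as x ~ x1 + x2 where x1 is sparse in a
# high-Q (oscillatory) TQWT dictionary Phi1 and x2 in a low-Q (transient)
# dictionary Phi2. The coefficients solve the dual basis-pursuit-denoising
# problem
#
#   argmin_{w1,w2} || x - Phi1' w1 - Phi2' w2 ||_2^2
#                  + sum_j lambda_{1,j} ||w_{1,j}||_1
#                  + sum_j lambda_{2,j} ||w_{2,j}||_1
#
# minimized by a SALSA (split augmented Lagrangian shrinkage) iteration
# with per-subband soft thresholding, run for a fixed number of
# iterations (500 by default).

## wavelet-norm cache: norms depend only on (Q, r, J, padded length)
.sw_norm_cache <- new.env(parent = emptyenv())

tqwt_wavelet_norms <- function(params, J, Np) {
  key <- sprintf("%.12g|%.12g|%d|%d", params$Q, params$r, J, Np)
  if (!is.null(.sw_norm_cache[[key]])) return(.sw_norm_cache[[key]])
  p <- tqwt_params(params$Q, params$r, J)
  nrm <- vapply(seq_len(J + 1L), function(j) {
    sqrt(sum(tqwt_synthesis_wavelet(p, j, Np)^2))
  }, numeric(1))
  .sw_norm_cache[[key]] <- nrm
  nrm
}

## padded length realizable for BOTH dictionaries
mca_common_padded_length <- function(N, p1, p2, J1, J2) {
  Np <- max(tqwt_padded_length(N, p1$alpha, p1$beta, J1),
            tqwt_padded_length(N, p2$alpha, p2$beta, J2))
  realizable <- function(Np, prm, J) {
    ln <- tqwt_subband_lengths(Np, prm$alpha, prm$beta, J)
    prev <- c(Np, ln$n0[-J])
    all(ln$n0 >= 4) && all(ln$n1 >= 4) && all(ln$n0 + ln$n1 - prev >= 2) &&
      all(ln$n1 <= prev) && all(ln$n0 <= prev)
  }
  while (!(realizable(Np, p1, J1) && realizable(Np, p2, J2))) Np <- Np + 2L
  Np
}

#' Dual-dictionary decomposition problem
#'
#' Bundles the two TQWT dictionaries, regularization weights and solver
#' settings for [dual_q_decompose()].
#'
#' @param params_osc [tqwt_params()] of the oscillatory (high-Q)
#'   dictionary; its Q must exceed `params_trans$Q`.
#' @param params_trans [tqwt_params()] of the transient (low-Q) dictionary.
#' @param lambdas_osc,lambdas_trans optional numeric vectors of
#'   non-negative per-subband L1 weights, lengths `J1 + 1` and `J2 + 1`;
#'   `NULL` (default) derives them with [default_lambdas()] at solve time.
#' @param n_iterations number of solver iterations (default 500).
#' @param theta_osc,theta_trans global regularization factors used when
#'   the lambdas are derived automatically (default 0.1 each).
#' @param mu augmented-Lagrangian step parameter of the `"salsa"` solver;
#'   `NULL` (default) uses `0.5 * mean(lambda) / scale`. Ignored by
#'   `"ista"`, whose step is fixed at `1/L = 0.25`.
#' @param solver `"fista"` (default; monotone accelerated proximal
#'   gradient — the objective trace is non-increasing by construction),
#'   `"ista"` (plain proximal gradient, also monotone but slower), or
#'   `"salsa"` (split augmented Lagrangian; similar convergence speed to
#'   `"fista"` but its objective trace may oscillate at fine scales).
#' @return An object of class `mca_problem`.
#' @export
mca_problem <- function(params_osc, params_trans,
                        lambdas_osc = NULL, lambdas_trans = NULL,
                        n_iterations = 500L,
                        theta_osc = 0.1, theta_trans = 0.1, mu = NULL,
                        solver = c("fista", "ista", "salsa")) {
  solver <- match.arg(solver)
  stopifnot(inherits(params_osc, "tqwt_params"),
            inherits(params_trans, "tqwt_params"))
  if (params_osc$Q <= params_trans$Q) {
    stop("the oscillatory dictionary must have the higher Q-factor",
         call. = FALSE)
  }
  if (!is.numeric(n_iterations) || n_iterations < 1) {
    stop("`n_iterations` must be a positive integer", call. = FALSE)
  }
  for (lam in list(lambdas_osc, lambdas_trans)) {
    if (!is.null(lam) && (!is.numeric(lam) || any(lam < 0))) {
      stop("lambda vectors must be non-negative numeric", call. = FALSE)
    }
  }
  structure(list(params_osc = params_osc, params_trans = params_trans,
                 lambdas_osc = lambdas_osc, lambdas_trans = lambdas_trans,
                 n_iterations = as.integer(n_iterations),
                 theta_osc = theta_osc, theta_trans = theta_trans, mu = mu,
                 solver = solver),
            class = "mca_problem")
}

#' Standard sleep-EEG decomposition preset
#'
#' The dictionary pair used throughout the package for sleep EEG:
#' Q = 5.5 (spindle-like, about the minimum number of cycles of an
#' 11-16 Hz burst lasting 0.5 s) for the oscillatory dictionary, Q = 1 for
#' the transient dictionary, redundancy r = 3 for both, and J = J_max for
#' the segment length at hand.
#'
#' @param ... passed on to [mca_problem()] (e.g. `n_iterations`).
#' @return An `mca_problem`.
#' @export
mca_preset_sleep <- function(...) {
  mca_problem(tqwt_params(Q = 5.5, r = 3), tqwt_params(Q = 1, r = 3), ...)
}

#' Default per-subband regularization weights
#'
#' `lambda_{i,j} = theta_i * ||psi_{i,j}||_2 * scale`, where
#' `||psi_{i,j}||_2` is the L2 norm of the level-j synthesis wavelet of
#' dictionary i (obtained by inverting a unit coefficient) and `scale` is
#' an amplitude scale of the signal (for example its standard deviation).
#' Scaling by the wavelet norms equalizes the penalty across subbands of
#' an overcomplete transform.
#'
#' @param problem an [mca_problem()].
#' @param N signal length in samples the weights are meant for.
#' @param scale positive amplitude scale of the signal, in the signal's
#'   units (microvolts).
#' @return List with `lambdas_osc`, `lambdas_trans` (strictly positive).
#' @export
default_lambdas <- function(problem, N, scale) {
  stopifnot(inherits(problem, "mca_problem"))
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop("`scale` must be a positive scalar", call. = FALSE)
  }
  rs <- mca_resolve(problem, N)
  list(lambdas_osc = problem$theta_osc * rs$norms1 * scale,
       lambdas_trans = problem$theta_trans * rs$norms2 * scale)
}

## resolve J per dictionary, common padded length and wavelet norms
mca_resolve <- function(problem, N) {
  p1 <- problem$params_osc; p2 <- problem$params_trans
  J1 <- if (is.null(p1$J)) tqwt_max_levels(N, p1$alpha, p1$beta) else p1$J
  J2 <- if (is.null(p2$J)) tqwt_max_levels(N, p2$alpha, p2$beta) else p2$J
  Np <- mca_common_padded_length(N, p1, p2, J1, J2)
  list(J1 = J1, J2 = J2, Np = Np,
       ln1 = tqwt_subband_lengths(Np, p1$alpha, p1$beta, J1),
       ln2 = tqwt_subband_lengths(Np, p2$alpha, p2$beta, J2),
       norms1 = tqwt_wavelet_norms(p1, J1, Np),
       norms2 = tqwt_wavelet_norms(p2, J2, Np))
}

#' Dual basis-pursuit-denoising objective
#'
#' Evaluates the squared residual plus the two weighted L1 penalty sums
#' for a candidate coefficient pair.
#'
#' @param x the signal.
#' @param w1,w2 `tqwt_subbands` coefficient sets for the two dictionaries.
#' @param lambdas_osc,lambdas_trans numeric weight vectors of lengths
#'   `J1 + 1` and `J2 + 1`.
#' @return Non-negative scalar.
#' @export
mca_objective <- function(x, w1, w2, lambdas_osc, lambdas_trans) {
  stopifnot(inherits(w1, "tqwt_subbands"), inherits(w2, "tqwt_subbands"))
  if (length(lambdas_osc) != length(w1$highpass) + 1L ||
      length(lambdas_trans) != length(w2$highpass) + 1L) {
    stop("lambda vector lengths must equal J + 1 for each dictionary",
         call. = FALSE)
  }
  res <- x - tqwt_inverse(w1) - tqwt_inverse(w2)
  l1 <- function(w, lam) {
    sum(vapply(seq_along(w$highpass),
               function(j) lam[j] * sum(abs(w$highpass[[j]])), numeric(1))) +
      lam[length(lam)] * sum(abs(w$lowpass))
  }
  sum(res^2) + l1(w1, lambdas_osc) + l1(w2, lambdas_trans)
}

#' Decompose a signal into oscillatory and transient components
#'
#' Runs the SALSA solver for the dual basis-pursuit-denoising problem and
#' returns the two morphological components together with their sparse
#' coefficients, the residual and the per-iteration objective trace.
#'
#' @param x real numeric signal (microvolts).
#' @param problem an [mca_problem()]; see [mca_preset_sleep()].
#' @param scale amplitude scale used for the automatic lambdas; default
#'   `stats::sd(x)`.
#' @return Object of class `mca_result`: list with `x1` (oscillatory),
#'   `x2` (transient), `w1`, `w2` (`tqwt_subbands`), `residual`
#'   (`x - x1 - x2`), `objective_trace`, `lambdas_osc`, `lambdas_trans`,
#'   `mu`.
#' @examples
#' \donttest{
#' fs <- 200
#' t <- seq(0, 2, by = 1 / fs)
#' x <- 30 * sin(2 * pi * 13 * t)
#' res <- dual_q_decompose(x, mca_preset_sleep(n_iterations = 100))
#' sum(res$x1^2) / sum(x^2)  # oscillatory component carries the tone
#' }
#' @export
dual_q_decompose <- function(x, problem = mca_preset_sleep(),
                             scale = stats::sd(x)) {
  stopifnot(inherits(problem, "mca_problem"))
  if (length(x) < 32L) stop("signal too short to decompose", call. = FALSE)
  if (!is.numeric(x) || !all(is.finite(x))) {
    stop("signal must be finite numeric", call. = FALSE)
  }
  x <- as.numeric(x)
  N <- length(x)
  rs <- mca_resolve(problem, N)

  make_subbands <- function(lst, prm, J, ln) {
    structure(list(highpass = lst[seq_len(J)], lowpass = lst[[J + 1L]],
                   params = tqwt_params(prm$Q, prm$r, J),
                   input_length = N, padded_length = rs$Np),
              class = "tqwt_subbands")
  }

  if (!is.finite(scale) || scale <= 0) {
    # zero (or constant-zero-scale) signal: trivial decomposition
    zf <- function(prm, J, ln) {
      make_subbands(c(lapply(ln$n1, numeric), list(numeric(ln$n0[J]))),
                    prm, J, ln)
    }
    w1 <- zf(problem$params_osc, rs$J1, rs$ln1)
    w2 <- zf(problem$params_trans, rs$J2, rs$ln2)
    return(structure(list(x1 = numeric(N), x2 = numeric(N), w1 = w1, w2 = w2,
                          residual = x, objective_trace = numeric(problem$n_iterations),
                          lambdas_osc = NULL, lambdas_trans = NULL, mu = NA_real_),
                     class = "mca_result"))
  }

  lam1 <- problem$lambdas_osc
  lam2 <- problem$lambdas_trans
  if (is.null(lam1) || is.null(lam2)) {
    dl <- default_lambdas(problem, N, scale)
    if (is.null(lam1)) lam1 <- dl$lambdas_osc
    if (is.null(lam2)) lam2 <- dl$lambdas_trans
  }
  if (length(lam1) != rs$J1 + 1L || length(lam2) != rs$J2 + 1L) {
    stop("lambda vector lengths must equal J + 1 for each dictionary",
         call. = FALSE)
  }
  mu <- problem$mu
  if (is.null(mu)) mu <- 0.5 * mean(c(lam1, lam2)) / scale
  if (!is.finite(mu) || mu <= 0) stop("invalid solver step `mu`", call. = FALSE)

  xp <- c(x, numeric(rs$Np - N))
  fit <- switch(problem$solver,
    salsa = .mca_salsa_cpp(xp,
                           as.integer(rs$ln1$n0), as.integer(rs$ln1$n1),
                           as.integer(rs$ln2$n0), as.integer(rs$ln2$n1),
                           lam1, lam2, mu, problem$n_iterations),
    ista = .mca_ista_cpp(xp,
                         as.integer(rs$ln1$n0), as.integer(rs$ln1$n1),
                         as.integer(rs$ln2$n0), as.integer(rs$ln2$n1),
                         lam1, lam2, problem$n_iterations),
    fista = .mca_fista_cpp(xp,
                           as.integer(rs$ln1$n0), as.integer(rs$ln1$n1),
                           as.integer(rs$ln2$n0), as.integer(rs$ln2$n1),
                           lam1, lam2, problem$n_iterations))

  trace <- as.numeric(fit$objective)
  incr <- diff(trace) > 1e-6 * max(trace[1], 1)
  if (length(incr) >= 20L && any(stats::filter(incr, rep(1, 20), sides = 1) == 20,
                                 na.rm = TRUE)) {
    cond <- structure(class = c("sleepwave_solver_error", "error", "condition"),
                      list(message = "solver objective diverged",
                           call = sys.call(), trace = trace))
    stop(cond)
  }

  w1 <- make_subbands(fit$w1, problem$params_osc, rs$J1, rs$ln1)
  w2 <- make_subbands(fit$w2, problem$params_trans, rs$J2, rs$ln2)
  x1 <- tqwt_inverse(w1)
  x2 <- tqwt_inverse(w2)
  structure(list(x1 = x1, x2 = x2, w1 = w1, w2 = w2,
                 residual = x - x1 - x2, objective_trace = trace,
                 lambdas_osc = lam1, lambdas_trans = lam2, mu = mu),
            class = "mca_result")
}

#' @export
print.mca_result <- function(x, ...) {
  n <- length(x$x1)
  cat(sprintf("MCA decomposition of %d samples\n", n))
  cat(sprintf("  energy: oscillatory %.1f%%, transient %.1f%%, residual %.1f%%\n",
              100 * sum(x$x1^2) / max(sum((x$x1 + x$x2 + x$residual)^2), 1e-12),
              100 * sum(x$x2^2) / max(sum((x$x1 + x$x2 + x$residual)^2), 1e-12),
              100 * sum(x$residual^2) / max(sum((x$x1 + x$x2 + x$residual)^2), 1e-12)))
  invisible(x)
}
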