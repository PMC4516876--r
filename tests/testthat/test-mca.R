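# Morphological component analysis: lambdas, objective, decomposition.

test_that("default lambdas have correct lengths, homogeneity and norms", {
  N <- 512
  prob <- mca_preset_sleep()
  dl <- default_lambdas(prob, N, scale = 10)
  rs <- sleepwave:::mca_resolve(prob, N)
  expect_length(dl$lambdas_osc, rs$J1 + 1L)    # J1 + 1 weights
  expect_length(dl$lambdas_trans, rs$J2 + 1L)  # J2 + 1 weights
  expect_true(all(dl$lambdas_osc > 0) && all(dl$lambdas_trans > 0))

  dl2 <- default_lambdas(prob, N, scale = 20)
  expect_equal(dl2$lambdas_osc, 2 * dl$lambdas_osc)
  expect_equal(dl2$lambdas_trans, 2 * dl$lambdas_trans)

  # wavelet norms match a brute-force unit-impulse synthesis
  p2 <- tqwt_params(1, 3, J = rs$J2)
  for (j in c(1L, rs$J2 + 1L)) {
    psi <- tqwt_synthesis_wavelet(p2, j, rs$Np)
    expect_equal(dl$lambdas_trans[j], prob$theta_trans * sqrt(sum(psi^2)) * 10,
                 tolerance = 1e-12)
  }
})

test_that("the objective evaluates the three terms of the criterion", {
  N <- 64
  prob <- mca_problem(tqwt_params(4, 3, J = 2), tqwt_params(1, 3, J = 2))
  x <- sin(2 * pi * 5 * (0:(N - 1)) / N)
  w1 <- tqwt_forward(numeric(N), prob$params_osc)
  w2 <- tqwt_forward(numeric(N), prob$params_trans)
  lam1 <- c(1, 2, 3); lam2 <- c(0.5, 0.25, 4)

  # all-zero coefficients -> ||x||^2
  expect_equal(mca_objective(x, w1, w2, lam1, lam2), sum(x^2))

  # single nonzero coefficient: brute-force evaluation of the three terms
  w1$highpass[[1]][5] <- 2
  w2$lowpass[3] <- -1.5
  manual <- sum((x - tqwt_inverse(w1) - tqwt_inverse(w2))^2) +
    lam1[1] * 2 + lam2[3] * 1.5
  expect_equal(mca_objective(x, w1, w2, lam1, lam2), manual, tolerance = 1e-12)

  # zero signal: objective >= penalties (residual is synthesis energy)
  obj0 <- mca_objective(numeric(N), w1, w2, lam1, lam2)
  expect_gte(obj0, lam1[1] * 2 + lam2[3] * 1.5)

  expect_error(mca_objective(x, w1, w2, c(1, 2), lam2), "lambda")
})

test_that("problem construction validates the dictionary pair", {
  expect_error(mca_problem(tqwt_params(1, 3), tqwt_params(5.5, 3)),
               "higher Q")
  expect_error(mca_problem(tqwt_params(5.5, 3), tqwt_params(1, 3),
                           lambdas_osc = c(-1, 2)), "non-negative")
  expect_error(mca_problem(tqwt_params(5.5, 3), tqwt_params(1, 3),
                           n_iterations = 0), "positive")
})

test_that("zero signal decomposes to zero with an all-zero trace", {
  res <- dual_q_decompose(numeric(512), mca_preset_sleep(n_iterations = 10))
  expect_true(all(res$x1 == 0) && all(res$x2 == 0))
  expect_true(all(res$objective_trace == 0))
  expect_equal(res$residual, numeric(512))
})

test_that("a pure tone goes to the oscillatory component", {
  fs <- fs_test
  x <- 30 * sin(2 * pi * 13 * seq(0, 2, by = 1 / fs))
  res <- dual_q_decompose(x, mca_preset_sleep(n_iterations = 500))
  etot <- sum(res$x1^2) + sum(res$x2^2) + sum(res$residual^2)
  expect_gte(sum(res$x1^2) / etot, 0.9)
})

test_that("a biphasic transient goes to the transient component", {
  x <- make_transient(trough = -75, dur = 0.7, total_s = 2)
  res <- dual_q_decompose(x, mca_preset_sleep(n_iterations = 500))
  etot <- sum(res$x1^2) + sum(res$x2^2) + sum(res$residual^2)
  expect_gte(sum(res$x2^2) / etot, 0.9)
})

test_that("tone + transient mixtures separate with high fidelity", {
  tone <- make_burst(freq = 13, dur = 1.2, amp = 30, total_s = 4)
  trans <- make_transient(trough = -75, dur = 0.7, total_s = 4, onset_s = 0.8)
  x <- tone + trans
  res <- dual_q_decompose(x, mca_preset_sleep(n_iterations = 400))
  expect_gte(cor(res$x1, tone), 0.9)
  expect_gte(cor(res$x2, trans), 0.9)
  expect_lte(sum(res$residual^2), 0.05 * sum(x^2))
  # additivity is exact by construction
  expect_lt(max(abs(res$x1 + res$x2 + res$residual - x)), 1e-10)
  # coefficient consistency: components are the synthesis of their subbands
  expect_lt(max(abs(res$x1 - tqwt_inverse(res$w1))), 1e-8)
  expect_lt(max(abs(res$x2 - tqwt_inverse(res$w2))), 1e-8)
})

test_that("objective trace is non-increasing on random inputs", {
  set.seed(21)
  for (rep in 1:20) {
    x <- rnorm(400, sd = 10)
    res <- dual_q_decompose(x, mca_preset_sleep(n_iterations = 60))
    tr <- res$objective_trace
    expect_true(all(diff(tr[-(1:5)]) <= 1e-9 * max(tr[1], 1)))
  }
})

test_that("sparsity: most coefficients vanish on band-limited input", {
  x <- make_burst(freq = 13, dur = 1, amp = 30, total_s = 2)
  res <- dual_q_decompose(x, mca_preset_sleep(n_iterations = 300))
  allw <- c(unlist(res$w1$highpass), res$w1$lowpass,
            unlist(res$w2$highpass), res$w2$lowpass)
  expect_gt(mean(abs(allw) < 1e-6 * max(abs(allw))), 0.5)
})

test_that("the solver is deterministic", {
  set.seed(5)
  x <- rnorm(400, sd = 10)
  r1 <- dual_q_decompose(x, mca_preset_sleep(n_iterations = 50))
  r2 <- dual_q_decompose(x, mca_preset_sleep(n_iterations = 50))
  expect_identical(r1$x1, r2$x1)
  expect_identical(r1$x2, r2$x2)
  expect_identical(r1$objective_trace, r2$objective_trace)
})
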