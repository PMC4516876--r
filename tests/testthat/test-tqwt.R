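# Tunable Q-factor wavelet transform: filter scalings, level bounds,
# frequency responses, perfect reconstruction.

test_that("filter scalings follow the defining relations and invert", {
  sc <- compute_filter_scalings(1, 3)
  expect_equal(unname(sc["alpha"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(sc["beta"]), 1, tolerance = 1e-12)

  sc <- compute_filter_scalings(5.5, 3)
  expect_equal(unname(sc["beta"]), 0.307692, tolerance = 1e-5)
  expect_equal(unname(sc["alpha"]), 0.897436, tolerance = 1e-5)

  # round trip: re-evaluating the defining formulas recovers (Q, r)
  for (qr in list(c(1, 3), c(5.5, 3), c(2.7, 4.2))) {
    sc <- compute_filter_scalings(qr[1], qr[2])
    a <- sc[["alpha"]]; b <- sc[["beta"]]
    expect_equal((2 - b) / b, qr[1], tolerance = 1e-12)
    expect_equal(b / (1 - a), qr[2], tolerance = 1e-12)
    expect_gt(a + b, 1)  # oversampling condition
  }

  expect_error(compute_filter_scalings(-1, 3), "Q")
  expect_error(compute_filter_scalings(1, 1), "r")
  expect_error(compute_filter_scalings(Inf, 3), "Q")
})

test_that("J_max matches the printed formula and its boundary", {
  expect_identical(tqwt_max_levels(1024, 2 / 3, 1), 11L)  # floor(log(128)/log(1.5))
  expect_identical(tqwt_max_levels(2048, 2 / 3, 1), 13L)  # floor(log(256)/log(1.5))

  # smallest N with J_max = 1 for (alpha, beta) = (2/3, 1): beta*N/8 >= 1/alpha
  a <- 2 / 3; b <- 1
  N1 <- ceiling(8 / (b * a))  # = 12 -> below the N >= 16 floor; use next J=1 case
  expect_identical(tqwt_max_levels(16, a, b), 1L)

  expect_error(tqwt_max_levels(16, a, beta = 0.4), "too short")

  # monotonicity: non-decreasing in N, non-increasing in beta at fixed N
  Ns <- c(64, 128, 256, 512, 1024, 4096)
  jm <- vapply(Ns, tqwt_max_levels, integer(1), alpha = a, beta = b)
  expect_true(all(diff(jm) >= 0))
  betas <- c(0.3, 0.5, 0.8, 1)
  jb <- vapply(betas, function(bb) {
    tqwt_max_levels(4096, 1 - bb / 3, bb)  # r = 3 fixed
  }, integer(1))
  expect_true(all(diff(jb) <= 0))
})

test_that("level frequency responses satisfy the cascade support conditions", {
  p <- tqwt_params(Q = 1, r = 3, J = 8)
  for (j in c(1L, 3L, 8L)) {
    fr <- tqwt_filter_response(p, j, grid_size = 4097L)  # odd: grid hits 0
    dc <- which.min(abs(fr$omega))
    expect_equal(fr$h0[dc], 1, tolerance = 1e-12)   # DC passes the low-pass cascade
    expect_equal(fr$h1[dc], 0, tolerance = 1e-12)   # high-pass kills DC
    out0 <- abs(fr$omega) > p$alpha^j * pi
    expect_true(all(fr$h0[out0] == 0))
    band1 <- abs(fr$omega) >= (1 - p$beta) * p$alpha^(j - 1) * pi &
      abs(fr$omega) <= p$alpha^(j - 1) * pi
    expect_true(all(fr$h1[!band1] == 0))
    # level 1 reaches unit gain; deeper cascade levels share energy with
    # their neighbours and peak lower
    expect_gte(max(fr$h1), if (j == 1L) 1 - 1e-12 else 0.5)
  }
  expect_error(tqwt_filter_response(p, 9), "level")
  expect_error(tqwt_filter_response(p, 0), "level")
})

test_that("perfect reconstruction across lengths, presets and random draws", {
  set.seed(42)
  for (qr in list(c(1, 3), c(5.5, 3))) {
    for (N in c(256, 500, 1024, 30 * fs_test)) {
      p <- tqwt_params(qr[1], qr[2], N = N)
      for (rep in 1:3) {
        x <- rnorm(N)
        w <- tqwt_forward(x, p)
        expect_length(w$highpass, p$J)            # J + 1 subbands in total
        xr <- tqwt_inverse(w)
        expect_lt(sqrt(sum((xr - x)^2) / sum(x^2)), 1e-8)
      }
    }
  }
})

test_that("impulse and zero-signal reconstruction are exact", {
  p <- tqwt_params(1, 3, N = 512)
  d <- numeric(512); d[100] <- 1
  expect_lt(max(abs(tqwt_inverse(tqwt_forward(d, p)) - d)), 1e-8)

  w0 <- tqwt_forward(numeric(512), p)
  expect_true(all(vapply(w0$highpass, function(v) all(v == 0), logical(1))))
  expect_true(all(w0$lowpass == 0))
  expect_true(all(tqwt_inverse(w0) == 0))
})

test_that("the inverse transform is linear", {
  set.seed(7)
  p <- tqwt_params(5.5, 3, N = 400)
  w1 <- tqwt_forward(rnorm(400), p)
  w2 <- tqwt_forward(rnorm(400), p)
  a <- 2.5; b <- -1.25
  comb <- w1
  comb$highpass <- Map(function(u, v) a * u + b * v, w1$highpass, w2$highpass)
  comb$lowpass <- a * w1$lowpass + b * w2$lowpass
  expect_lt(max(abs(tqwt_inverse(comb) -
                      (a * tqwt_inverse(w1) + b * tqwt_inverse(w2)))), 1e-10)
})

test_that("energy is preserved (Parseval frame) and redundancy ~ r", {
  set.seed(3)
  ratios <- replicate(20, {
    x <- rnorm(1024)
    w <- tqwt_forward(x, tqwt_params(1, 3, N = 1024))
    (sum(unlist(w$highpass)^2) + sum(w$lowpass^2)) / sum(x^2)
  })
  expect_true(all(is.finite(ratios)))
  expect_lt(diff(range(ratios)) / mean(ratios), 0.01)
  expect_equal(mean(ratios), 1, tolerance = 1e-10)

  w <- tqwt_forward(rnorm(6000), tqwt_params(5.5, 3, N = 6000))
  red <- (sum(vapply(w$highpass, length, 1L)) + length(w$lowpass)) / 6000
  expect_equal(red, 3, tolerance = 0.05)
})

test_that("a 13 Hz tone concentrates where the level responses say it should", {
  fs <- fs_test
  N <- 2 * fs
  x <- sin(2 * pi * 13 * (0:(N - 1)) / fs)
  p <- tqwt_params(5.5, 3, N = N)
  w <- tqwt_forward(x, p)

  # oracle: per-level high-pass response evaluated at 13 Hz
  omega13 <- 2 * pi * 13 / fs
  resp <- vapply(seq_len(p$J), function(j) {
    fr <- tqwt_filter_response(p, j, grid_size = 8192L)
    fr$h1[which.min(abs(fr$omega - omega13))]
  }, numeric(1))
  top2 <- order(-resp)[1:2]

  en <- vapply(w$highpass, function(v) sum(v^2), numeric(1))
  etot <- sum(en) + sum(w$lowpass^2)
  expect_gte(sum(en[top2]) / etot, 0.9)
})

test_that("compiled cascade matches the pure-R reference", {
  set.seed(11)
  for (qr in list(c(1, 3), c(5.5, 3))) {
    N <- 500
    p <- tqwt_params(qr[1], qr[2], N = N)
    x <- rnorm(N)
    w <- tqwt_forward(x, p)
    Np <- w$padded_length
    ln <- sleepwave:::tqwt_subband_lengths(Np, p$alpha, p$beta, p$J)
    ref <- sleepwave:::tqwt_forward_ref(c(x, numeric(Np - N)), ln$n0, ln$n1)
    expect_lt(max(mapply(function(a, b) max(abs(a - b)),
                         c(w$highpass, list(w$lowpass)), ref)), 1e-12)
    xr_ref <- sleepwave:::tqwt_inverse_ref(ref, Np, ln$n0, ln$n1)[seq_len(N)]
    expect_lt(max(abs(tqwt_inverse(w) - xr_ref)), 1e-12)
  }
})

test_that("invalid inputs are rejected", {
  p <- tqwt_params(1, 3)
  expect_error(tqwt_forward(numeric(0), p), "empty")
  expect_error(tqwt_forward(c(1, NA, 3), p), "finite")
  expect_error(tqwt_forward(rnorm(64), tqwt_params(1, 3, J = 30)), "J_max")
  expect_error(tqwt_params(1, 3, J = 30, N = 64), "J_max")
  w <- tqwt_forward(rnorm(256), tqwt_params(1, 3, N = 256))
  w$highpass[[1]] <- w$highpass[[1]][-1]
  expect_error(tqwt_inverse(w), "inconsistent")
})
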