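# fbsp wavelet, CWT map, 2-D maxima, spindle event building, wavelet
# ranking.

test_that("fbsp wavelet matches its closed form", {
  expect_equal(fbsp_wavelet(0, m = 25L, fb = 1, fc = 7), 1 + 0i)
  expect_equal(fbsp_wavelet(0, m = 3L, fb = 1, fc = 1), 1 + 0i)

  t <- seq(-5, 5, by = 0.01)
  v <- fbsp_wavelet(t, m = 25L)
  expect_equal(Mod(v), rev(Mod(v)), tolerance = 1e-12)  # even envelope

  # quadrature oracle for the energy integral
  emp <- sum(Mod(fbsp_wavelet(seq(-40, 40, by = 1e-3), m = 5L))^2) * 1e-3
  orc <- stats::integrate(function(u) Mod(fbsp_wavelet(u, m = 5L))^2,
                          -40, 40, subdivisions = 2000L)$value
  expect_equal(emp, orc, tolerance = 1e-4)

  expect_error(fbsp_wavelet(0, m = 0L), "m")
  expect_error(fbsp_wavelet(0, fb = -1), "fb")
})

test_that("the CWT map localizes tones and scales quadratically", {
  fs <- fs_test
  n <- 4 * fs
  zero_map <- cwt_tfmap(numeric(n), fs)
  expect_true(all(zero_map$values == 0))
  expect_equal(dim(zero_map$values), c(21L, n))

  x <- sin(2 * pi * 13 * (0:(n - 1)) / fs)
  m1 <- cwt_tfmap(x, fs)
  rowmean <- rowMeans(m1$values)
  expect_equal(m1$freqs[which.max(rowmean)], 13, tolerance = 0.26)

  m2 <- cwt_tfmap(2 * x, fs)
  expect_equal(m2$values, 4 * m1$values, tolerance = 1e-10)

  expect_error(cwt_tfmap(x, fs, freqs = c(10, 12)), "band")
  expect_error(cwt_tfmap(x, fs = 20), "fs")
})

test_that("2-D maxima match the brute-force scan", {
  v <- matrix(0, 3, 3); v[2, 2] <- 1
  mx <- local_maxima_2d(v)
  expect_equal(nrow(mx), 1L)
  expect_equal(unlist(mx[1, ]), c(freq_idx = 2, time_idx = 2, value = 1))

  expect_equal(nrow(local_maxima_2d(matrix(1, 5, 5))), 0L)  # plateau

  set.seed(9)
  for (rep in 1:10) {
    v <- matrix(runif(2500), 50, 50)
    got <- local_maxima_2d(v)
    ref <- brute_maxima_2d(v)
    expect_equal(nrow(got), nrow(ref))
    got_s <- got[order(got$freq_idx, got$time_idx), ]
    expect_equal(got_s$freq_idx, ref[order(ref[, 1], ref[, 2]), 1])
    expect_equal(got_s$time_idx, ref[order(ref[, 1], ref[, 2]), 2])
  }

  expect_error(local_maxima_2d(matrix(1, 2, 5)), "3 rows")
})

test_that("spindle events honour threshold, duration floor and localization", {
  fs <- fs_test
  x <- make_burst(freq = 13, dur = 0.8, amp = 30, total_s = 4, center_s = 2)
  map <- cwt_tfmap(x, fs)
  peak <- max(map$values)

  expect_equal(nrow(detect_spindles(map, threshold = 2 * peak)), 0L)

  ev <- detect_spindles(map, threshold = peak / 4)
  expect_equal(nrow(ev), 1L)
  expect_lt(ev$start_s, 2); expect_gt(ev$end_s, 2)       # overlaps the burst
  expect_gte(ev$end_s - ev$start_s, 0.5)
  expect_lt(abs(ev$peak_time_s - 2), 0.25)               # peak localization

  # too-short blob: 0.3 s of supra-threshold power is rejected
  xs <- make_burst(freq = 13, dur = 0.3, amp = 30, total_s = 4, center_s = 2)
  maps <- cwt_tfmap(xs, fs)
  expect_equal(nrow(detect_spindles(maps, threshold = max(maps$values) / 4)), 0L)
  # and at the lower band edge, where the wavelet smear is widest
  xs11 <- make_burst(freq = 11.5, dur = 0.3, amp = 30, total_s = 4, center_s = 2)
  maps11 <- cwt_tfmap(xs11, fs)
  expect_equal(nrow(detect_spindles(maps11, threshold = max(maps11$values) / 4)), 0L)

  expect_error(detect_spindles(map, threshold = -5), "threshold")
})

test_that("spindle count is non-increasing in the threshold", {
  fs <- fs_test
  set.seed(33)
  x <- make_burst(13, 1, 30, total_s = 8, center_s = 2) +
    make_burst(14.5, 0.7, 18, total_s = 8, center_s = 5) +
    rnorm(8 * fs, sd = 2)
  map <- cwt_tfmap(x, fs)
  thr <- seq(0, max(map$values) * 1.1, length.out = 25)
  counts <- vapply(thr, function(tt) nrow(detect_spindles(map, tt)), integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 0L)
})

test_that("wavelet ranking behaves and prefers fbsp on spindle bursts", {
  fs <- fs_test
  wv <- Re(fbsp_wavelet(seq(-0.6, 0.6, by = 1 / fs) * 13, m = 25L))
  self <- waveform_crosscorr(list(wv), fs)
  expect_equal(unname(self$correlations[1, "fbsp"]), 1, tolerance = 1e-6)
  expect_true(all(self$correlations >= -1 & self$correlations <= 1))

  set.seed(4)
  snippets <- lapply(1:12, function(i) {
    make_burst(freq = runif(1, 12, 14), dur = runif(1, 0.6, 1.2),
               amp = 20, total_s = 2, center_s = 1) + rnorm(2 * fs, sd = 1)
  })
  cc <- waveform_crosscorr(snippets, fs)
  med <- cc$summary$median
  names(med) <- cc$summary$wavelet
  expect_gte(med["fbsp"], med["gauss"])

  expect_error(waveform_crosscorr(list(), fs), "non-empty")
  expect_error(waveform_crosscorr(list(rnorm(10)), fs), "0.5 s")
})
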