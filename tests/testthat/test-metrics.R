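# Matching, Sen/FDR, threshold sweeps, agreement, RMS baseline.

mk_ev <- function(kind, starts, durs = 1, seg = 1L) {
  sw_events(kind, seg, starts, starts + durs)
}

test_that("matching handles identical, disjoint and ambiguous sets", {
  a <- mk_ev("spindle", c(1, 5, 9, 13, 17))
  m <- match_events(a, a)
  expect_equal(c(m$TP, m$FP, m$FN), c(5L, 0L, 0L))

  d <- mk_ev("spindle", c(1, 5, 9))
  ann <- mk_ev("spindle", c(30, 35, 40, 45))
  m <- match_events(d, ann)
  expect_equal(c(m$TP, m$FP, m$FN), c(0L, 3L, 4L))

  # kinds and segments never cross-match
  m <- match_events(mk_ev("spindle", 1), mk_ev("kcomplex", 1))
  expect_equal(m$TP, 0L)
  m <- match_events(mk_ev("spindle", 1, seg = 1L), mk_ev("spindle", 1, seg = 2L))
  expect_equal(m$TP, 0L)

  # one-to-one: two detections over one annotation -> 1 TP, 1 FP
  m <- match_events(mk_ev("spindle", c(1, 1.4)), mk_ev("spindle", 1.2))
  expect_equal(c(m$TP, m$FP, m$FN), c(1L, 1L, 0L))

  expect_warning(match_events(mk_ev("spindle", 1),
                              mk_ev("spindle", c(2, 2))), "duplicate")
})

test_that("greedy matching equals the exhaustive count on non-ambiguous sets", {
  set.seed(2)
  for (rep in 1:10) {
    # non-ambiguous: one annotation per 10-s slot, detections jittered
    slots <- sample(1:50, 25)
    ann <- mk_ev("spindle", slots * 10, durs = 1.5)
    hit <- sort(sample(seq_along(slots), 15))
    det <- mk_ev("spindle", slots[hit] * 10 + runif(15, -0.5, 0.5), durs = 1.2)
    extra <- mk_ev("spindle", sample(setdiff(1:50, slots), 5) * 10 + 3)
    det <- bind_events(det, extra)
    m <- match_events(det, ann)
    expect_equal(m$TP, 15L)              # exhaustive count by construction
    expect_equal(m$FP, nrow(det) - 15L)
    expect_equal(m$FN, nrow(ann) - 15L)
  }
})

test_that("Sen and FDR follow their defining ratios", {
  mm <- function(tp, fp, fn) structure(list(TP = tp, FP = fp, FN = fn),
                                       class = "sw_match")
  expect_equal(sensitivity(mm(5, 0, 5)), 0.5)
  expect_equal(sensitivity(mm(0, 0, 7)), 0)
  expect_equal(sensitivity(mm(7, 0, 0)), 1)
  expect_true(is.na(sensitivity(mm(0, 3, 0))))   # undefined, not 0

  expect_equal(fdr(mm(3, 1, 0)), 0.25)
  expect_equal(fdr(mm(5, 0, 2)), 0)
  expect_equal(fdr(mm(0, 4, 1)), 1)
  expect_true(is.na(fdr(mm(0, 0, 4))))           # undefined, not 0
})

test_that("threshold sweep and optimal threshold follow argmax(Sen - FDR)", {
  # direct argmax examples
  cv <- list(thresholds = c(10, 20, 30), sens = c(1, 1, 0.5),
             fdr = c(0.9, 0.2, 0.1))
  expect_equal(optimal_threshold(cv), 20)
  cv$sens <- c(0.7, 0.7, 0.7); cv$fdr <- c(0.2, 0.2, 0.2)
  expect_equal(optimal_threshold(cv), 10)        # tie -> first

  set.seed(6)
  for (rep in 1:20) {                            # exhaustive-scan oracle
    cv <- list(thresholds = 1:15, sens = runif(15), fdr = runif(15))
    expect_equal(optimal_threshold(cv),
                 cv$thresholds[which.max(cv$sens - cv$fdr)])
  }
  expect_error(optimal_threshold(list(thresholds = numeric())), "empty")
})

test_that("sweeping a synthetic score detector lands between the classes", {
  set.seed(10)
  # event peaks ~ N(8, 2) at known slots; background maxima ~ N(4, 2)
  ann <- mk_ev("spindle", (1:40) * 10, durs = 2)
  ev_val <- rnorm(40, 8, 2)
  bg_start <- (1:60) * 10 + 5
  bg_val <- rnorm(60, 4, 2)
  detector <- function(thr) {
    keep_e <- ev_val > thr
    keep_b <- bg_val > thr
    bind_events(
      if (any(keep_e)) mk_ev("spindle", (which(keep_e)) * 10 + 0.2, 1.5),
      if (any(keep_b)) mk_ev("spindle", bg_start[keep_b], 1.5))
  }
  curve <- threshold_sweep(detector, ann, seq(0, 14, by = 0.5))
  expect_true(all(diff(curve$n_detected) <= 0))  # count monotonicity
  best <- optimal_threshold(curve)
  expect_gt(best, 4); expect_lt(best, 8)         # between the two means

  # trivial construction: all events far above any threshold
  curve2 <- threshold_sweep(function(thr) {
    if (max(ev_val + 100) > thr) mk_ev("spindle", (1:40) * 10 + 0.1, 1.5) else
      sw_events()
  }, ann, c(1, 5, 9))
  expect_true(all(curve2$sens == 1))

  expect_error(threshold_sweep(detector, sw_events(), 1:3), "no annotated")
})

test_that("sweep consistency: the best pair is reproduced when re-applied", {
  set.seed(10)
  ann <- mk_ev("spindle", (1:30) * 10, durs = 2)
  vals <- rnorm(30, 8, 2)
  bg <- rnorm(40, 4, 2)
  detector <- function(thr) {
    bind_events(
      if (any(vals > thr)) mk_ev("spindle", which(vals > thr) * 10 + 0.2, 1.5),
      if (any(bg > thr)) mk_ev("spindle", (1:40)[bg > thr] * 10 + 5, 1.5))
  }
  curve <- threshold_sweep(detector, ann, seq(0, 14, by = 0.5))
  best <- optimal_threshold(curve)
  m <- match_events(detector(best), ann)
  b <- curve$best_index
  expect_equal(sensitivity(m), curve$sens[b])
  expect_equal(fdr(m), curve$fdr[b])
})

test_that("agreement reproduces the hand-computed kappa fixtures", {
  ann <- mk_ev("spindle", (1:30) * 5, seg = 1:30)
  ag <- agreement(ann, ann, 40)
  expect_equal(ag$percent_agreement, 100)
  expect_equal(ag$kappa, 1)

  # 2x2 fixture: a=40, b=10, c=10, d=40 over 100 segments -> kappa = 0.6
  a_seg <- 1:50            # annotator A positive on 50 segments
  b_seg <- c(1:40, 51:60)  # annotator B: 40 shared + 10 others
  ag <- agreement(mk_ev("spindle", a_seg * 200, seg = a_seg),
                  mk_ev("spindle", b_seg * 200, seg = b_seg), 100)
  expect_equal(ag$percent_agreement, 80)
  expect_equal(ag$kappa, 0.6, tolerance = 1e-12)

  # independent random annotators: kappa ~ 0
  set.seed(17)
  n <- 1000
  a_seg <- which(runif(n) < 0.4)
  b_seg <- which(runif(n) < 0.4)
  ag <- agreement(mk_ev("spindle", a_seg, seg = a_seg, durs = 0.5),
                  mk_ev("spindle", b_seg, seg = b_seg, durs = 0.5), n)
  expect_lt(abs(ag$kappa), 0.1)

  # kappa <= percent agreement / 100 on all these fixtures
  expect_lte(ag$kappa, ag$percent_agreement / 100)
})

test_that("the RMS baseline matches the analytic amplitude/sqrt(2) rule", {
  fs <- fs_test
  expect_equal(nrow(rms_baseline_detect(numeric(10 * fs), fs, threshold = 10)), 0L)

  # 1-s 13 Hz burst of amplitude 30 uV: RMS = 30/sqrt(2) = 21.2 > 10
  t <- (0:(10 * fs - 1)) / fs
  x <- numeric(10 * fs)
  on <- t >= 4 & t < 5
  x[on] <- 30 * sin(2 * pi * 13 * t[on])
  ev <- rms_baseline_detect(x, fs, threshold = 10)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$end_s - ev$start_s, 1, tolerance = 0.21)
  expect_equal(ev$peak_value, 30 / sqrt(2), tolerance = 0.1 * 30 / sqrt(2))

  # amplitude below sqrt(2) * T stays undetected
  x2 <- numeric(10 * fs)
  x2[on] <- 12 * sin(2 * pi * 13 * t[on])   # RMS 8.5 < 10
  expect_equal(nrow(rms_baseline_detect(x2, fs, threshold = 10)), 0L)

  # a 4-s supra-threshold run is rejected by the 3-s cap
  x3 <- numeric(10 * fs)
  on3 <- t >= 3 & t < 7
  x3[on3] <- 30 * sin(2 * pi * 13 * t[on3])
  expect_equal(nrow(rms_baseline_detect(x3, fs, threshold = 10)), 0L)

  expect_error(rms_baseline_detect(x, fs, threshold = -1), "threshold")
})
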