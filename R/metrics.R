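# Event matching, sensitivity / FDR, threshold training and agreement.
#
# Detected and annotated events are matched one-to-one, greedily by
# largest temporal overlap; any positive overlap qualifies under the
# default criterion. Sensitivity = TP / (TP + FN), FDR = FP / (FP + TP).
# Thresholds are trained by sweeping the detector threshold over training
# segments and picking argmax(Sen - FDR), the ROC-like operating point.

#' Match detected events against annotations
#'
#' Greedy one-to-one assignment by decreasing temporal overlap; each
#' detected event matches at most one annotation and vice versa. Events
#' of different `kind` or different `segment_id` never match.
#'
#' @param detected,annotated [sw_events()] tables.
#' @param min_overlap_s minimum overlap to qualify as a match; the
#'   default 0 means any positive overlap.
#' @return Object of class `sw_match`: list with `TP`, `FP`, `FN` and
#'   `matched_pairs` (data.frame of detected / annotated row indices and
#'   overlaps).
#' @export
match_events <- function(detected, annotated, min_overlap_s = 0) {
  dup <- duplicated(annotated[, c("kind", "segment_id", "start_s", "end_s")])
  if (any(dup)) {
    warning(sprintf("%d duplicate annotation(s) kept", sum(dup)), call. = FALSE)
  }
  nd <- nrow(detected); na <- nrow(annotated)
  pairs <- data.frame(det = integer(), ann = integer(), overlap = numeric())
  if (nd > 0L && na > 0L) {
    cand <- expand.grid(det = seq_len(nd), ann = seq_len(na))
    ov <- pmin(detected$end_s[cand$det], annotated$end_s[cand$ann]) -
      pmax(detected$start_s[cand$det], annotated$start_s[cand$ann])
    ok <- ov > min_overlap_s &
      detected$kind[cand$det] == annotated$kind[cand$ann] &
      detected$segment_id[cand$det] == annotated$segment_id[cand$ann]
    cand <- cand[ok, , drop = FALSE]
    ov <- ov[ok]
    if (nrow(cand) > 0L) {
      ord <- order(-ov)
      used_d <- logical(nd); used_a <- logical(na)
      keep <- logical(nrow(cand))
      for (k in ord) {
        if (!used_d[cand$det[k]] && !used_a[cand$ann[k]]) {
          used_d[cand$det[k]] <- TRUE
          used_a[cand$ann[k]] <- TRUE
          keep[k] <- TRUE
        }
      }
      pairs <- data.frame(det = cand$det[keep], ann = cand$ann[keep],
                          overlap = ov[keep])
    }
  }
  tp <- nrow(pairs)
  structure(list(TP = tp, FP = nd - tp, FN = na - tp, matched_pairs = pairs),
            class = "sw_match")
}

#' @export
print.sw_match <- function(x, ...) {
  cat(sprintf("event matching: TP = %d, FP = %d, FN = %d (Sen %.3f, FDR %.3f)\n",
              x$TP, x$FP, x$FN, sensitivity(x), fdr(x)))
  invisible(x)
}

#' Sensitivity (recall) of a match result
#'
#' `TP / (TP + FN)`. Returns `NA` when no events were annotated
#' (undefined metric, distinct from 0).
#'
#' @param m an `sw_match` from [match_events()].
#' @return Fraction in `[0, 1]`, or `NA_real_`.
#' @export
sensitivity <- function(m) {
  stopifnot(inherits(m, "sw_match"))
  if (m$TP + m$FN == 0L) return(NA_real_)
  m$TP / (m$TP + m$FN)
}

#' False discovery rate of a match result
#'
#' `FP / (FP + TP)`. Returns `NA` when nothing was detected (undefined
#' metric, distinct from 0).
#'
#' @inheritParams sensitivity
#' @return Fraction in `[0, 1]`, or `NA_real_`.
#' @export
fdr <- function(m) {
  stopifnot(inherits(m, "sw_match"))
  if (m$TP + m$FP == 0L) return(NA_real_)
  m$FP / (m$FP + m$TP)
}

#' Sweep a detection threshold against annotations
#'
#' Runs `detector(threshold)` for every threshold, pools the detections
#' over all segments, and records sensitivity and FDR against the
#' annotations. Spindle thresholds are swept upward in microvolt^2
#' steps; K-complex thresholds downward in (negative) microvolt steps —
#' pass the thresholds in the order meaningful for the detector; the
#' curve stores them as given.
#'
#' @param detector function of one argument (the threshold) returning an
#'   [sw_events()] table pooled over the training segments.
#' @param annotated [sw_events()] annotations over the same segments;
#'   must contain at least one event.
#' @param thresholds numeric vector of thresholds to try.
#' @return Object of class `sw_threshold_curve`: list with `thresholds`,
#'   `sens`, `fdr`, `n_detected` and `best_index`
#'   (`argmax(sens - fdr)`, first index on ties; `fdr = NA` counts as 0
#'   false discoveries for the difference since nothing was detected).
#' @export
threshold_sweep <- function(detector, annotated, thresholds) {
  if (nrow(annotated) == 0L) {
    stop("no annotated events: sweep metrics are undefined", call. = FALSE)
  }
  if (length(thresholds) == 0L) stop("empty threshold grid", call. = FALSE)
  sens <- fdrv <- numeric(length(thresholds))
  ndet <- integer(length(thresholds))
  for (i in seq_along(thresholds)) {
    det <- detector(thresholds[i])
    m <- match_events(det, annotated)
    sens[i] <- sensitivity(m)
    fdrv[i] <- fdr(m)
    ndet[i] <- nrow(det)
  }
  crit <- ifelse(is.na(sens), -Inf, sens) - ifelse(is.na(fdrv), 0, fdrv)
  structure(list(thresholds = thresholds, sens = sens, fdr = fdrv,
                 n_detected = ndet, best_index = which.max(crit)),
            class = "sw_threshold_curve")
}

#' @export
print.sw_threshold_curve <- function(x, ...) {
  b <- x$best_index
  cat(sprintf("threshold sweep over %d values; best = %g (Sen %.3f, FDR %.3f)\n",
              length(x$thresholds), x$thresholds[b], x$sens[b],
              ifelse(is.na(x$fdr[b]), 0, x$fdr[b])))
  invisible(x)
}

#' Optimal threshold of a sweep curve
#'
#' The threshold maximizing `sens - fdr` (first index on ties).
#'
#' @param curve an `sw_threshold_curve` from [threshold_sweep()], or a
#'   list with `thresholds`, `sens`, `fdr`.
#' @return Scalar threshold.
#' @export
optimal_threshold <- function(curve) {
  if (length(curve$thresholds) == 0L) stop("empty curve", call. = FALSE)
  crit <- ifelse(is.na(curve$sens), -Inf, curve$sens) -
    ifelse(is.na(curve$fdr), 0, curve$fdr)
  if (all(!is.finite(crit))) stop("all metrics undefined", call. = FALSE)
  curve$thresholds[which.max(crit)]
}

#' Inter-annotator agreement on segment-level presence
#'
#' Each annotator is reduced to a binary per-segment presence/absence
#' vector for the given event kind; percent agreement and Cohen's kappa
#' `(p_o - p_e) / (1 - p_e)` are computed over segments.
#'
#' @param annot_a,annot_b [sw_events()] tables from the two annotators.
#' @param n_segments total number of segments scored by both.
#' @param kind event kind to compare (`"spindle"` or `"kcomplex"`).
#' @return Object of class `sw_agreement`: list with `percent_agreement`
#'   (0-100), `kappa`, and the 2x2 `table`. `kappa` is `NA` when the
#'   chance agreement `p_e` equals 1 (both annotators constant).
#' @export
agreement <- function(annot_a, annot_b, n_segments, kind = "spindle") {
  pres <- function(an) {
    v <- logical(n_segments)
    seg <- an$segment_id[an$kind == kind]
    v[seg[seg >= 1 & seg <= n_segments]] <- TRUE
    v
  }
  a <- pres(annot_a); b <- pres(annot_b)
  tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                nrow = 2L, byrow = TRUE,
                dimnames = list(A = c("yes", "no"), B = c("yes", "no")))
  po <- (tab[1L, 1L] + tab[2L, 2L]) / n_segments
  pa <- sum(a) / n_segments; pb <- sum(b) / n_segments
  pe <- pa * pb + (1 - pa) * (1 - pb)
  kappa <- if (abs(1 - pe) < .Machine$double.eps^0.5) NA_real_ else (po - pe) / (1 - pe)
  structure(list(percent_agreement = 100 * po, kappa = kappa, table = tab),
            class = "sw_agreement")
}

#' @export
print.sw_agreement <- function(x, ...) {
  cat(sprintf("agreement: %.1f%%, Cohen's kappa = %s\n", x$percent_agreement,
              ifelse(is.na(x$kappa), "NA", sprintf("%.3f", x$kappa))))
  invisible(x)
}

#' RMS baseline spindle detector
#'
#' The classical fixed-threshold method used for comparison: band-pass
#' the raw EEG (12-15 Hz), compute the RMS of consecutive 100 ms
#' windows, and report maximal runs of windows whose RMS exceeds the
#' threshold `T` when the run lasts between `min_dur_s` and `max_dur_s`.
#'
#' @param x raw EEG, microvolts.
#' @param fs sampling rate in Hz.
#' @param threshold RMS threshold `T` in microvolts (> 0).
#' @param band band edges in Hz (default `c(12, 15)`).
#' @param window_s RMS window length (default 0.1 s).
#' @param min_dur_s,max_dur_s admissible run duration (defaults 0.5 and 3 s).
#' @param segment_id optional segment label.
#' @return An [sw_events()] table of spindles; `peak_value` is the peak
#'   window RMS in microvolts.
#' @export
rms_baseline_detect <- function(x, fs, threshold, band = c(12, 15),
                                window_s = 0.1, min_dur_s = 0.5,
                                max_dur_s = 3, segment_id = 1L) {
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("`threshold` must be > 0 (microvolts RMS)", call. = FALSE)
  }
  xf <- bandpass(as.numeric(x), fs, band[1L], band[2L])
  wlen <- round(window_s * fs)
  nwin <- floor(length(xf) / wlen)
  if (nwin == 0L) return(sw_events())
  rms <- sqrt(colMeans(matrix(xf[seq_len(nwin * wlen)], nrow = wlen)^2))
  above <- rms > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  if (length(runs) == 0L) return(sw_events())
  dur <- r$lengths[runs] * window_s
  keep <- dur >= min_dur_s & dur <= max_dur_s
  runs <- runs[keep]
  if (length(runs) == 0L) return(sw_events())
  st <- (starts[runs] - 1L) * window_s
  en <- ends[runs] * window_s
  pk <- vapply(runs, function(k) max(rms[starts[k]:ends[k]]), numeric(1))
  pt <- vapply(runs, function(k) {
    (starts[k] - 1L + which.max(rms[starts[k]:ends[k]]) - 0.5) * window_s
  }, numeric(1))
  sw_events(kind = "spindle", segment_id = segment_id,
            start_s = st, end_s = en, peak_value = pk, peak_time_s = pt)
}
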