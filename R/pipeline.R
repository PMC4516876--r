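# The full detection pipeline, per 30-s segment:
#   preprocess (0.2-40 Hz) -> TQWT-MCA decomposition -> spindle CWT map on
#   the oscillatory component + K-complex FIR filtering on the transient
#   component -> thresholded detection, events re-indexed to recording
#   time. With `use_mca = FALSE` the decomposition is skipped (the
#   ablation configuration): the CWT runs on the preprocessed raw signal
#   and the K-complex filter on the raw signal directly.

#' Pipeline configuration
#'
#' @param spindle_threshold detection threshold on the time-frequency map
#'   (microvolt^2); train it with [train_thresholds()].
#' @param kc_threshold K-complex trough threshold (negative microvolts).
#' @param use_mca if `FALSE`, skip the TQWT-MCA decomposition (ablation).
#' @param n_iterations MCA solver iterations (default 500).
#' @param solver MCA solver, see [mca_problem()].
#' @param freqs CWT analysis frequencies (Hz) inside the spindle band.
#' @param spindle_max_duration_s optional spindle duration cap (`NULL`:
#'   none).
#' @param kc pass a [kc_config()] to change the K-complex filter/band
#'   settings; its `threshold` is overridden by `kc_threshold`.
#' @param preprocess_band artifact filter edges in Hz.
#' @param segment_s segment length in seconds.
#' @return Object of class `sw_config` (a list).
#' @export
pipeline_config <- function(spindle_threshold = 100,
                            kc_threshold = -70,
                            use_mca = TRUE,
                            n_iterations = 500L,
                            solver = "fista",
                            freqs = seq(11, 16, by = 0.25),
                            spindle_max_duration_s = NULL,
                            kc = kc_config(),
                            preprocess_band = c(0.2, 40),
                            segment_s = 30) {
  kc$threshold <- kc_threshold
  structure(list(spindle_threshold = spindle_threshold,
                 kc_threshold = kc_threshold, use_mca = use_mca,
                 n_iterations = as.integer(n_iterations), solver = solver,
                 freqs = freqs,
                 spindle_max_duration_s = spindle_max_duration_s, kc = kc,
                 preprocess_band = preprocess_band, segment_s = segment_s),
            class = "sw_config")
}

#' Per-segment detector features
#'
#' Runs the expensive pipeline stages once (preprocessing, decomposition,
#' CWT map, K-complex band-pass) so that thresholds can then be swept or
#' applied cheaply. Used by both [train_thresholds()] and
#' [run_pipeline()].
#'
#' @param x raw EEG in microvolts.
#' @param fs sampling rate in Hz.
#' @param config a [pipeline_config()].
#' @param verbose print one progress line per segment.
#' @return Object of class `sw_features`: list of per-segment lists
#'   (`tfmap`, `kc_filtered`, `segment_id`) plus `fs` and `config`.
#' @export
pipeline_features <- function(x, fs, config = pipeline_config(),
                              verbose = FALSE) {
  stopifnot(inherits(config, "sw_config"))
  x <- as.numeric(x)
  segs <- segment_indices(length(x), fs, config$segment_s)
  if (length(segs) == 0L) stop("recording shorter than one segment", call. = FALSE)
  kern_pre <- fir_bandpass_design(fs, config$preprocess_band[1L],
                                  config$preprocess_band[2L])
  feats <- vector("list", length(segs))
  for (s in seq_along(segs)) {
    t0 <- proc.time()[3L]
    # strictly per-segment processing (segment independence contract)
    xi <- fir_filter(x[segs[[s]]], kern_pre)
    if (config$use_mca) {
      dec <- dual_q_decompose(xi, mca_preset_sleep(
        n_iterations = config$n_iterations, solver = config$solver))
      osc <- dec$x1
      trans <- dec$x2
    } else {
      osc <- xi
      trans <- xi
    }
    tfmap <- cwt_tfmap(osc, fs, freqs = config$freqs, segment_id = s)
    feats[[s]] <- list(
      tfmap = tfmap,
      sp_candidates = spindle_candidates(
        tfmap, max_duration_s = config$spindle_max_duration_s),
      kc_filtered = kc_bandpass(trans, fs, config$kc),
      segment_id = s)
    if (verbose) {
      message(sprintf("segment %d/%d: features in %.1f s", s, length(segs),
                      proc.time()[3L] - t0))
    }
  }
  structure(list(segments = feats, fs = fs, config = config),
            class = "sw_features")
}

## apply thresholds to precomputed features; events in recording time
detect_from_features <- function(features, spindle_threshold, kc_threshold,
                                 kinds = c("spindle", "kcomplex")) {
  config <- features$config
  fs <- features$fs
  out <- list()
  for (f in features$segments) {
    off <- (f$segment_id - 1L) * config$segment_s
    if ("spindle" %in% kinds) {
      sp <- detect_spindles(f$tfmap, spindle_threshold,
                            max_duration_s = config$spindle_max_duration_s,
                            candidates = f$sp_candidates)
      if (nrow(sp) > 0L) {
        sp$segment_id <- f$segment_id
        sp$start_s <- sp$start_s + off
        sp$end_s <- sp$end_s + off
        sp$peak_time_s <- sp$peak_time_s + off
        out[[length(out) + 1L]] <- sp
      }
    }
    if ("kcomplex" %in% kinds) {
      kcfg <- config$kc
      kcfg$threshold <- kc_threshold
      kc <- detect_kcomplexes(f$kc_filtered, fs, kcfg,
                              segment_id = f$segment_id)
      if (nrow(kc) > 0L) {
        kc$start_s <- kc$start_s + off
        kc$end_s <- kc$end_s + off
        kc$peak_time_s <- kc$peak_time_s + off
        out[[length(out) + 1L]] <- kc
      }
    }
  }
  do.call(bind_events, out)
}

#' Train detection thresholds on annotated segments
#'
#' Sweeps the spindle threshold upward (10 microvolt^2 steps, up to twice
#' the largest map value) and the K-complex threshold downward (2
#' microvolt steps to -200), computes pooled sensitivity and FDR against
#' the annotations at each value, and selects `argmax(sens - fdr)` for
#' each event type.
#'
#' @param features an `sw_features` from [pipeline_features()] over the
#'   training recording.
#' @param annotations [sw_events()] ground truth for the same segments
#'   (times in recording seconds).
#' @param spindle_grid,kc_grid optional explicit threshold grids.
#' @return List with `spindle_threshold`, `kc_threshold`,
#'   `spindle_curve`, `kc_curve` (class `sw_training`).
#' @export
train_thresholds <- function(features, annotations,
                             spindle_grid = NULL, kc_grid = NULL) {
  stopifnot(inherits(features, "sw_features"))
  res <- list()
  if (is.null(spindle_grid)) {
    mx <- max(vapply(features$segments,
                     function(f) max(f$tfmap$values), numeric(1)))
    spindle_grid <- seq(0, 2 * mx, by = 10)
  }
  if (is.null(kc_grid)) kc_grid <- seq(-2, -200, by = -2)

  ann_sp <- annotations[annotations$kind == "spindle", , drop = FALSE]
  ann_kc <- annotations[annotations$kind == "kcomplex", , drop = FALSE]

  sp_curve <- if (nrow(ann_sp) > 0L) {
    threshold_sweep(function(thr) {
      detect_from_features(features, thr, -1, kinds = "spindle")
    }, ann_sp, spindle_grid)
  } else NULL
  kc_curve <- if (nrow(ann_kc) > 0L) {
    threshold_sweep(function(thr) {
      detect_from_features(features, Inf, thr, kinds = "kcomplex")
    }, ann_kc, kc_grid)
  } else NULL

  structure(list(
    spindle_threshold = if (is.null(sp_curve)) NA_real_ else optimal_threshold(sp_curve),
    kc_threshold = if (is.null(kc_curve)) NA_real_ else optimal_threshold(kc_curve),
    spindle_curve = sp_curve, kc_curve = kc_curve),
    class = "sw_training")
}

#' @export
print.sw_training <- function(x, ...) {
  cat(sprintf("trained thresholds: spindle %.1f uV^2, K-complex %.1f uV\n",
              x$spindle_threshold, x$kc_threshold))
  invisible(x)
}

#' Run the full detection pipeline on a recording
#'
#' @param x raw EEG in microvolts.
#' @param fs sampling rate in Hz.
#' @param config a [pipeline_config()] carrying the (trained) thresholds.
#' @param features optionally, precomputed [pipeline_features()] for `x`
#'   (skips recomputation).
#' @param verbose print per-segment progress.
#' @return List with `spindles`, `kcomplexes` ([sw_events()] in recording
#'   time) and `report` (settings and per-segment counts; serializable to
#'   JSON).
#' @export
run_pipeline <- function(x, fs, config = pipeline_config(), features = NULL,
                         verbose = FALSE) {
  if (is.null(features)) {
    features <- pipeline_features(x, fs, config, verbose = verbose)
  }
  ev <- detect_from_features(features, config$spindle_threshold,
                             config$kc_threshold)
  sp <- ev[ev$kind == "spindle", , drop = FALSE]
  kc <- ev[ev$kind == "kcomplex", , drop = FALSE]
  n_seg <- length(features$segments)
  report <- list(
    n_segments = n_seg, fs = fs,
    use_mca = config$use_mca, n_iterations = config$n_iterations,
    spindle_threshold = config$spindle_threshold,
    kc_threshold = config$kc_threshold,
    n_spindles = nrow(sp), n_kcomplexes = nrow(kc),
    spindles_per_segment = as.integer(tabulate(sp$segment_id, n_seg)),
    kcomplexes_per_segment = as.integer(tabulate(kc$segment_id, n_seg)))
  list(spindles = sp, kcomplexes = kc, report = report)
}

#' Evaluate detections against reference annotations
#'
#' @param detected,reference [sw_events()] tables.
#' @return List with per-kind `TP`, `FP`, `FN`, `sensitivity`, `fdr`
#'   (ready for JSON serialization).
#' @export
evaluate_detection <- function(detected, reference) {
  per_kind <- function(kind) {
    m <- match_events(detected[detected$kind == kind, , drop = FALSE],
                      reference[reference$kind == kind, , drop = FALSE])
    list(TP = m$TP, FP = m$FP, FN = m$FN,
         sensitivity = sensitivity(m), fdr = fdr(m))
  }
  list(spindle = per_kind("spindle"), kcomplex = per_kind("kcomplex"))
}
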