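# Synthetic sleep-EEG generator with ground truth.
#
# Emulates the two AASM-defined microstructures on a 1/f^gamma Gaussian
# background: spindles are Gaussian-windowed 11-16 Hz tone bursts lasting
# 0.5-2 s, K-complexes are smooth biphasic waves (negative sharp lobe
# immediately followed by a positive lobe at half the trough amplitude).
# Events never overlap and successive K-complexes keep a 2-s guard, so
# ground-truth matching stays unambiguous. The background is stationary
# colored noise - no sleep-stage architecture, no EOG/EMG or movement
# artifacts - so detector performance on it bounds above what real
# recordings would give.

## evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' Defaults describe a plausible central-channel stage-2 sleep EEG:
#' 10 microvolt RMS 1/f background, 1.5 spindles and 1 K-complex per 30-s
#' segment, spindle amplitudes 15-40 microvolts, K-complex troughs -75 to
#' -150 microvolts.
#'
#' @param fs sampling rate in Hz (>= 100; default 200).
#' @param n_segments number of 30-s segments (default 20).
#' @param segment_s segment length in seconds (default 30).
#' @param spindle_rate,kc_rate expected events per segment (Poisson).
#' @param spindle_freq_range spindle frequency range in Hz, inside 11-16.
#' @param spindle_dur_range spindle duration range in seconds (>= 0.5).
#' @param spindle_amp_range spindle envelope peak range in microvolts.
#' @param kc_trough_range K-complex trough range, negative microvolts.
#' @param kc_dur_range K-complex duration range in seconds.
#' @param background_gamma spectral exponent of the 1/f^gamma background.
#' @param noise_scale background RMS in microvolts.
#' @param seed integer seed making the recording reproducible.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(fs = 200, n_segments = 20L, segment_s = 30,
                       spindle_rate = 1.5, kc_rate = 1,
                       spindle_freq_range = c(11, 16),
                       spindle_dur_range = c(0.5, 2),
                       spindle_amp_range = c(15, 40),
                       kc_trough_range = c(-150, -75),
                       kc_dur_range = c(0.5, 1.5),
                       background_gamma = 1, noise_scale = 10,
                       seed = 1L) {
  stopifnot(fs >= 100, n_segments >= 1, segment_s > 0,
            spindle_rate >= 0, kc_rate >= 0,
            diff(spindle_freq_range) >= 0, spindle_freq_range[1] >= 11,
            spindle_freq_range[2] <= 16,
            diff(spindle_dur_range) >= 0, spindle_dur_range[1] >= 0.5,
            diff(spindle_amp_range) >= 0, spindle_amp_range[1] > 0,
            diff(kc_trough_range) >= 0, kc_trough_range[2] < 0,
            diff(kc_dur_range) >= 0, kc_dur_range[1] >= 0.5,
            noise_scale >= 0)
  structure(as.list(environment()), class = "sim_config")
}

#' 1/f^gamma Gaussian background
#'
#' White Gaussian noise spectrally shaped to power ~ f^(-gamma) (DC
#' removed) and rescaled to the requested RMS. Deterministic per seed.
#'
#' @param n_samples length of the output.
#' @param fs sampling rate in Hz.
#' @param gamma spectral exponent (default 1).
#' @param noise_scale target RMS in microvolts.
#' @param seed integer seed, or `NULL` to draw from the current RNG state.
#' @return Numeric vector of length `n_samples`.
#' @export
generate_background <- function(n_samples, fs, gamma = 1, noise_scale = 10,
                                seed = NULL) {
  if (noise_scale == 0) return(numeric(n_samples))
  with_seed(seed, {
    w <- stats::rnorm(n_samples)
    f <- c(0, pmin(seq_len(n_samples - 1L), n_samples - seq_len(n_samples - 1L))) *
      fs / n_samples
    shape <- c(0, f[-1L]^(-gamma / 2))
    x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE)) / n_samples
    x <- x - mean(x)
    x * noise_scale / sqrt(mean(x^2))
  })
}

#' Spindle waveform template
#'
#' Gaussian-windowed sinusoid: envelope peak exactly `amp` at the centre,
#' envelope standard deviation `dur/6` (the burst visually starts and
#' ends at the `dur` boundaries).
#'
#' @param dur duration in seconds (>= 0.5).
#' @param freq oscillation frequency in Hz (11-16 for spindles).
#' @param amp envelope peak in microvolts.
#' @param fs sampling rate in Hz.
#' @return Numeric vector of odd length `<= dur * fs + 1`.
#' @export
spindle_template <- function(dur, freq, amp, fs) {
  half <- floor(dur * fs / 2)
  t <- (-half:half) / fs
  amp * exp(-0.5 * (t / (dur / 6))^2) * cos(2 * pi * freq * t)
}

#' K-complex waveform template
#'
#' Smooth (C1) biphasic wave: a negative half-sine-squared lobe reaching
#' exactly `trough_amp`, immediately followed by a positive lobe peaking
#' at half the trough magnitude; total duration `dur`.
#'
#' @param dur total duration in seconds (>= 0.5).
#' @param trough_amp trough amplitude in microvolts (negative).
#' @param fs sampling rate in Hz.
#' @return Numeric vector of length about `dur * fs`.
#' @export
kcomplex_template <- function(dur, trough_amp, fs) {
  stopifnot(trough_amp < 0)
  n1 <- 2L * floor(0.55 * dur * fs / 2) + 1L  # odd: exact peak sample
  n2 <- 2L * floor(0.45 * dur * fs / 2) + 1L
  neg <- trough_amp * sin(pi * (seq_len(n1) - 1L) / (n1 - 1L))^2
  pos <- (-0.5 * trough_amp) * sin(pi * (seq_len(n2) - 1L) / (n2 - 1L))^2
  c(neg, pos[-1L])
}

#' Generate a synthetic recording with ground truth
#'
#' Background plus Poisson-placed, non-overlapping spindle and K-complex
#' templates; placements keep 0.25 s between any two events and 2 s
#' between consecutive K-complexes. Deterministic per `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return Object of class `sw_recording`: list with `signal`
#'   (microvolts), `fs`, `truth` ([sw_events()] with exact intervals;
#'   `peak_value` is the injected amplitude), `config`.
#' @export
generate_recording <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  seg_n <- round(cfg$segment_s * cfg$fs)
  # infeasibility guard: expected occupancy above ~80% cannot be placed
  occ <- cfg$spindle_rate * (max(cfg$spindle_dur_range) + 0.25) +
    cfg$kc_rate * (max(cfg$kc_dur_range) + 2)
  if (occ > 0.8 * cfg$segment_s) {
    stop("event rates infeasible under the non-overlap/guard constraints",
         call. = FALSE)
  }
  with_seed(cfg$seed, {
    signal <- generate_background(seg_n * cfg$n_segments, cfg$fs,
                                  cfg$background_gamma, cfg$noise_scale,
                                  seed = NULL)
    runif1 <- function(r) stats::runif(1, r[1], r[2])
    ev <- list()
    for (seg in seq_len(cfg$n_segments)) {
      placed <- data.frame(kind = character(), start = numeric(),
                           end = numeric())
      n_sp <- stats::rpois(1, cfg$spindle_rate)
      n_kc <- stats::rpois(1, cfg$kc_rate)
      # K-complexes first (tighter guard), then spindles
      todo <- c(rep("kcomplex", n_kc), rep("spindle", n_sp))
      for (kind in todo) {
        dur <- if (kind == "spindle") runif1(cfg$spindle_dur_range) else
          runif1(cfg$kc_dur_range)
        ok <- FALSE
        for (try in 1:200) {
          st <- stats::runif(1, 0.5, cfg$segment_s - dur - 0.5)
          en <- st + dur
          guard <- ifelse(placed$kind == "kcomplex" & kind == "kcomplex", 2, 0.25)
          if (all(st >= placed$end + guard | en <= placed$start - guard)) {
            ok <- TRUE; break
          }
        }
        if (!ok) next  # skip unplaceable event (rates remain feasible on average)
        placed <- rbind(placed, data.frame(kind = kind, start = st, end = en))
        i0 <- (seg - 1L) * seg_n + round(st * cfg$fs) + 1L
        if (kind == "spindle") {
          freq <- runif1(cfg$spindle_freq_range)
          amp <- runif1(cfg$spindle_amp_range)
          tpl <- spindle_template(dur, freq, amp, cfg$fs)
          pk <- amp
          pt <- (i0 - 1 + (length(tpl) - 1) / 2) / cfg$fs
        } else {
          amp <- runif1(cfg$kc_trough_range)
          tpl <- kcomplex_template(dur, amp, cfg$fs)
          pk <- amp
          pt <- (i0 - 1 + (which.min(tpl) - 1)) / cfg$fs
        }
        idx <- i0:(i0 + length(tpl) - 1L)
        signal[idx] <- signal[idx] + tpl
        ev[[length(ev) + 1L]] <- data.frame(
          kind = kind, segment_id = seg,
          start_s = (i0 - 1) / cfg$fs,
          end_s = (i0 - 1 + length(tpl)) / cfg$fs,
          peak_value = pk, peak_time_s = pt)
      }
    }
    truth <- if (length(ev)) {
      do.call(bind_events, lapply(ev, function(d) {
        sw_events(d$kind, d$segment_id, d$start_s, d$end_s, d$peak_value,
                  d$peak_time_s)
      }))
    } else sw_events()
    structure(list(signal = signal, fs = cfg$fs, truth = truth, config = cfg),
              class = "sw_recording")
  })
}

#' @export
print.sw_recording <- function(x, ...) {
  cat(sprintf("synthetic recording: %.0f s at %g Hz, %d spindles, %d K-complexes\n",
              length(x$signal) / x$fs, x$fs,
              sum(x$truth$kind == "spindle"), sum(x$truth$kind == "kcomplex")))
  invisible(x)
}
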