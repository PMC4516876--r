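# Shared fixtures: clean oscillatory / transient test signals.

fs_test <- 200

## Gaussian-windowed tone burst (spindle-like), centred in a window
make_burst <- function(freq = 13, dur = 1, amp = 30, fs = fs_test,
                       total_s = 4, center_s = total_s / 2) {
  t <- (seq_len(round(total_s * fs)) - 1) / fs
  amp * exp(-0.5 * ((t - center_s) / (dur / 6))^2) *
    cos(2 * pi * freq * (t - center_s))
}

## biphasic K-complex-like transient embedded in zeros
make_transient <- function(trough = -75, dur = 0.7, fs = fs_test,
                           total_s = 4, onset_s = total_s / 2 - dur / 2) {
  x <- numeric(total_s * fs)
  tpl <- kcomplex_template(dur, trough, fs)
  i0 <- round(onset_s * fs) + 1L
  x[i0:(i0 + length(tpl) - 1L)] <- tpl
  x
}

## brute-force strict 8-neighbour maxima scan (independent oracle)
brute_maxima_2d <- function(v) {
  out <- NULL
  for (i in 2:(nrow(v) - 1)) {
    for (j in 2:(ncol(v) - 1)) {
      nb <- v[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (v[i, j] > max(nb[-5])) {
        out <- rbind(out, c(i, j, v[i, j]))
      }
    }
  }
  out
}

## brute-force strict local minima scan
brute_minima_1d <- function(x) {
  idx <- which(vapply(2:(length(x) - 1), function(i) {
    x[i] < x[i - 1] && x[i] < x[i + 1]
  }, logical(1))) + 1L
  data.frame(index = idx, value = x[idx])
}
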