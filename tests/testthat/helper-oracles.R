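# Independent oracles and small fixture builders shared across the suite.

# Naive O(N * L) coefficient-normalized cross-correlation: the brute-force
# reference for the FFT implementation.  Positive lag k scores
# sum(ref[i] * sec[i + k]).
naive_xcorr <- function(ref, sec, max_lag) {
  n <- length(ref)
  denom <- sqrt(sum(ref^2) * sum(sec^2))
  lags <- (-max_lag):max_lag
  vals <- vapply(lags, function(k) {
    i <- seq_len(n)
    j <- i + k
    ok <- j >= 1L & j <= n
    sum(ref[i[ok]] * sec[j[ok]])
  }, numeric(1))
  data.frame(lag = lags, value = vals / denom)
}

# Constant-orientation recording (gravity on z) of `n` samples.
flat_recording <- function(n, fs = 30, ...) {
  acc_recording(matrix(rep(c(0, 0, 1), each = n), n, 3), fs = fs, ...)
}

# Recording with a z-axis sinusoidal burst on top of gravity.
burst_recording <- function(n, fs = 30, burst_at = NULL, amp = 0.5,
                            freq = 2, ...) {
  t <- (seq_len(n) - 1) / fs
  z <- rep(1, n)
  if (is.null(burst_at)) burst_at <- c(t[1], t[n])
  sel <- t >= burst_at[1] & t < burst_at[2]
  z[sel] <- z[sel] + amp * sin(2 * pi * freq * t[sel])
  acc_recording(cbind(0, 0, z), fs = fs, ...)
}

# A dense activity script for short recordings: one movement bout per
# `bout_every_s`, starting at `first_at_s`.
dense_script <- function(duration_s, bout_every_s = 1200, bout_s = 240,
                         first_at_s = 60, kind = "walk", amplitude_g = 0.6,
                         step_hz = 2) {
  starts <- seq(first_at_s, duration_s - bout_s - 1, by = bout_every_s)
  kinds <- rep(kind, length.out = length(starts))
  activity_script(data.frame(start_s = starts, duration_s = bout_s,
                             kind = kinds, amplitude_g = amplitude_g,
                             step_hz = step_hz))
}
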