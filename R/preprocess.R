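# Stage I pre-processing: ENMO -> dead-band -> zero-phase band-pass -> abs.
# The step order matters (dead-banding a filtered signal is not the same as
# filtering a dead-banded one) and is fixed to the listed order.

#' Euclidean Norm Minus One (ENMO)
#'
#' Per-sample vector magnitude of triaxial acceleration minus 1 g, the
#' standard gravity-removed movement metric.  The value is signed here;
#' rectification happens at the end of the Stage I pipeline, and the hourly
#' activity gate uses `mean(abs(enmo))`.
#'
#' @param rec an [acc_recording()].
#' @return numeric vector, `sqrt(x^2 + y^2 + z^2) - 1`, in g.
#' @examples
#' enmo(acc_recording(matrix(c(0, 0, 1), 1, 3), fs = 30))  # 0 at rest
#' @export
enmo <- function(rec) {
  stopifnot(inherits(rec, "acc_recording"))
  .Call(accelalign_enmo, rec$data)
}

#' Dead-band thresholding
#'
#' Zeroes samples whose magnitude does not exceed a noise floor, keeping only
#' acceleration larger than the threshold.
#'
#' @param sig numeric vector (signed).
#' @param threshold noise floor in g; values with `abs(v) <= threshold` are
#'   set to 0.  Default 0.068 g.
#' @return numeric vector of the same length.
#' @export
dead_band <- function(sig, threshold = 0.068) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("config error: dead-band threshold must be a single value >= 0")
  sig[abs(sig) <= threshold] <- 0
  sig
}

# Butterworth band-pass design. `order` is the total band-pass order (poles),
# i.e. order/2 per band edge; exposed in config because "4th order band-pass"
# is ambiguous between the total and the prototype order.
butter_bandpass <- function(fs, low = 0.1, high = 7, order = 4) {
  if (order < 2 || order %% 2 != 0)
    stop("config error: band-pass order must be a positive even total order")
  if (!(low > 0 && low < high && high < fs / 2))
    stop("config error: need 0 < low < high < fs/2 (Nyquist)")
  signal::butter(order / 2, c(low, high) * 2 / fs, type = "pass")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero time delay) filtering with a Butterworth band-pass.
#' The effective magnitude response is the square of the single-pass response
#' and the phase response is identically zero.  Edge transients are suppressed
#' by odd-reflection padding of length `3 * order` at both ends, which is
#' trimmed after filtering; edge samples are still best excluded from
#' amplitude assertions.
#'
#' @param sig numeric vector.
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz (defaults 0.1 and 7).
#' @param order total band-pass filter order (even; default 4, i.e. 2 poles
#'   per edge).
#' @return filtered numeric vector, same length as `sig`.
#' @export
bandpass_zero_phase <- function(sig, fs, low = 0.1, high = 7, order = 4) {
  flt <- butter_bandpass(fs, low, high, order)
  n <- length(sig)
  pad <- min(3L * order, n - 1L)
  if (pad > 0L) {
    pre <- 2 * sig[1L] - sig[(pad + 1L):2L]
    post <- 2 * sig[n] - sig[(n - 1L):(n - pad)]
    x <- c(pre, sig, post)
  } else {
    x <- sig
  }
  b <- flt$b / flt$a[1L]
  a <- flt$a / flt$a[1L]
  y <- .Call(accelalign_filtfilt, b, a, as.double(x))
  y[(pad + 1L):(pad + n)]
}

# Squared single-pass magnitude response of the designed band-pass at
# frequency f (Hz) -- the analytic zero-phase gain, evaluated directly from
# the transfer-function coefficients.  Used as an independent check of the
# time-domain filtering path.
bandpass_gain2 <- function(f, fs, low = 0.1, high = 7, order = 4) {
  flt <- butter_bandpass(fs, low, high, order)
  w <- 2 * pi * f / fs
  z <- exp(-1i * w * (seq_along(flt$b) - 1L))
  h <- sum(flt$b * z) / sum(flt$a * z)
  Mod(h)^2
}

#' Stage I pre-processing pipeline
#'
#' Converts a 30 Hz triaxial recording into the single-channel movement
#' signal used for lag estimation: ENMO, then dead-band thresholding, then
#' zero-phase Butterworth band-pass filtering, then rectification (absolute
#' value), in that order.
#'
#' @param rec an [acc_recording()] at the working rate.
#' @param config an [alignment_config()] list (controls the dead-band level
#'   and filter parameters).
#' @param enmo_values optional pre-computed [enmo()] vector for `rec`, to
#'   avoid recomputation when the caller also needs the raw ENMO for the
#'   activity gate.
#' @return an [acc_signal()]; non-negative, same length as the input.
#' @export
preprocess_stage1 <- function(rec, config = alignment_config(),
                              enmo_values = NULL) {
  stopifnot(inherits(rec, "acc_recording"))
  e <- if (is.null(enmo_values)) enmo(rec) else enmo_values
  e <- dead_band(e, config$deadband_g)
  e <- bandpass_zero_phase(e, fs = rec$fs, low = config$bp_low_hz,
                           high = config$bp_high_hz, order = config$bp_order)
  acc_signal(abs(e), fs = rec$fs, source = rec$device_id)
}
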