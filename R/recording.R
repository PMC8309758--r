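#' Triaxial acceleration recording
#'
#' Container for a uniformly sampled triaxial acceleration stream in gravity
#' units (g).  The timebase is implicit: sample `i` (1-based) lies at
#' `start_time + (i - 1) / fs` seconds.  Uniform sampling is assumed by every
#' downstream stage.
#'
#' @param data numeric matrix or data frame with three columns (x, y, z), in g.
#' @param fs nominal sampling rate in Hz (> 0).
#' @param start_time recording start as numeric UTC seconds (epoch). Default 0.
#' @param device_id opaque device label.
#' @param wear_site one of `"hip"`, `"wrist"`, `"thigh"`, `"other"`.
#' @param range_g accelerometer measurement range in g; all samples must lie
#'   within `[-range_g, range_g]`. Default 8 (the common +-8 g raw mode).
#' @param validate check finiteness and range of every sample (default
#'   `TRUE`).  Internal transformations that provably preserve validity
#'   (resampling, trimming, the synthetic generator) skip the re-scan of
#'   multi-day arrays.
#' @return an object of class `acc_recording`.
#' @examples
#' rec <- acc_recording(matrix(c(0, 0, 1), 10, 3, byrow = TRUE), fs = 30)
#' n_samples(rec)
#' duration_s(rec)
#' @export
acc_recording <- function(data, fs, start_time = 0, device_id = "unknown",
                          wear_site = c("other", "hip", "wrist", "thigh"),
                          range_g = 8, validate = TRUE) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (ncol(data) != 3L)
    stop("triaxial recording requires exactly 3 columns (x, y, z)")
  if (nrow(data) < 1L)
    stop("recording must contain at least one sample")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  if (validate) {
    if (anyNA(data) || !all(is.finite(data)))
      stop("acceleration values must all be finite")
    if (max(abs(data)) > range_g)
      stop(sprintf("acceleration exceeds the +-%g g measurement range",
                   range_g))
  }
  wear_site <- match.arg(wear_site)
  colnames(data) <- c("x", "y", "z")
  structure(
    list(data = data, fs = fs, start_time = as.numeric(start_time),
         device_id = as.character(device_id), wear_site = wear_site,
         range_g = range_g),
    class = "acc_recording")
}

#' Number of samples in a recording
#' @param rec an `acc_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(rec) nrow(rec$data)

#' Recording duration
#'
#' Time from the first to the last sample, `(n - 1) / fs` seconds.
#' @param rec an `acc_recording`.
#' @return duration in seconds.
#' @export
duration_s <- function(rec) (nrow(rec$data) - 1L) / rec$fs

#' @export
print.acc_recording <- function(x, ...) {
  cat(sprintf("<acc_recording> %s @ %s\n", x$device_id, x$wear_site))
  cat(sprintf("  %d samples @ %g Hz (%.1f h), start %.3f s\n",
              nrow(x$data), x$fs, duration_s(x) / 3600, x$start_time))
  invisible(x)
}

#' Single-channel processed movement signal
#'
#' Output of the Stage I pre-processing pipeline: a rectified (non-negative)
#' ENMO-derived signal at the working sampling rate.
#'
#' @param values numeric vector, in g.
#' @param fs sampling rate in Hz.
#' @param source device label of the originating recording.
#' @return an object of class `acc_signal`.
#' @export
acc_signal <- function(values, fs, source = "unknown") {
  stopifnot(is.numeric(values), length(values) >= 1L, fs > 0)
  structure(list(values = as.numeric(values), fs = fs,
                 source = as.character(source)),
            class = "acc_signal")
}

#' @export
print.acc_signal <- function(x, ...) {
  cat(sprintf("<acc_signal> from %s: %d samples @ %g Hz\n",
              x$source, length(x$values), x$fs))
  invisible(x)
}
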