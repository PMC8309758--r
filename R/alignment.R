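# Stage III: apply the estimated initial offset and drift by trimming or
# prepending samples and resampling the secondary stream onto the reference
# timebase.

#' Apply an integer sample offset
#'
#' A positive offset (secondary running late) removes that many samples from
#' the beginning of the recording; a negative offset prepends samples.
#' Prepended samples replicate the first sample (a gravity-consistent hold):
#' zero-g triples are physically impossible at rest and would corrupt the
#' downstream ENMO.
#'
#' @param rec an [acc_recording()].
#' @param offset_samples integer; `abs(offset_samples)` must be smaller than
#'   the recording length.
#' @return an [acc_recording()].
#' @export
apply_offset <- function(rec, offset_samples) {
  stopifnot(inherits(rec, "acc_recording"))
  k <- as.integer(round(offset_samples))
  n <- nrow(rec$data)
  if (abs(k) >= n)
    stop("offset magnitude must be smaller than the recording length")
  data <- if (k > 0L) {
    rec$data[(k + 1L):n, , drop = FALSE]
  } else if (k < 0L) {
    rbind(rec$data[rep(1L, -k), , drop = FALSE], rec$data)
  } else {
    rec$data
  }
  acc_recording(data, fs = rec$fs, start_time = rec$start_time,
                device_id = rec$device_id, wear_site = rec$wear_site,
                range_g = rec$range_g, validate = FALSE)
}

#' Resample a recording under a linear clock map
#'
#' Warps the sample grid to undo a linear clock drift: output sample `n`
#' (0-based) reads the source stream at position
#' `phase + n * (1 + drift_samples_per_s / fs)`.  Positions beyond the last
#' source sample are truncated (the dropped count is reported as an
#' attribute).  Interpolation is per axis:
#' * `"previous"` (default): previous-neighbour hold -- creates no new
#'   amplitude values, preserving the signal's amplitude set and hence its
#'   frequency content for intensity metrics;
#' * `"linear"`: linear interpolation;
#' * `"cubic"`: shape-preserving piecewise-cubic interpolation.
#'
#' @param rec an [acc_recording()].
#' @param drift_samples_per_s drift slope, samples per second.
#' @param method `"previous"`, `"linear"` or `"cubic"`.
#' @param phase constant fractional source-sample offset added to every
#'   warped position (used to fold the fractional part of the initial offset
#'   into the warp). Default 0.
#' @return an [acc_recording()] at the same rate; `attr(, "n_truncated")`
#'   gives the number of output samples dropped at the end.
#' @export
apply_drift_resample <- function(rec, drift_samples_per_s,
                                 method = c("previous", "linear", "cubic"),
                                 phase = 0) {
  stopifnot(inherits(rec, "acc_recording"))
  method <- match.arg(method)
  step <- 1 + drift_samples_per_s / rec$fs
  if (step <= 0) stop("drift implies a non-monotone clock map")
  n_src <- nrow(rec$data)
  n_out <- floor(((n_src - 1L) - phase) / step) + 1L
  if (n_out < 1L) stop("phase/drift leave no samples in range")
  p <- phase + (seq_len(n_out) - 1L) * step
  out <- switch(method,
    previous = rec$data[floor(p + 1e-9) + 1L, , drop = FALSE],
    linear = {
      src_t <- seq_len(n_src) - 1L
      vapply(1:3, function(j) stats::approx(src_t, rec$data[, j], xout = p)$y,
             numeric(n_out))
    },
    cubic = {
      src_t <- seq_len(n_src) - 1L
      vapply(1:3, function(j)
        signal::interp1(src_t, rec$data[, j], p, method = "pchip"),
        numeric(n_out))
    })
  res <- acc_recording(out, fs = rec$fs, start_time = rec$start_time,
                       device_id = rec$device_id, wear_site = rec$wear_site,
                       range_g = rec$range_g, validate = FALSE)
  attr(res, "n_truncated") <- n_src - n_out
  res
}

#' Align a secondary recording to the reference timebase
#'
#' Applies a fitted alignment estimate to the secondary recording: first the
#' initial offset (trim/prepend), then the drift warp.  By default the
#' integer part of `beta0` is trimmed (`floor`) and the fractional remainder
#' enters the warp as a constant phase, avoiding a systematic half-sample
#' bias; with `config$round_offset = TRUE` the offset is rounded away
#' instead (the strict trim-by-rounded-offset variant).
#'
#' @param ref the reference [acc_recording()] (hip-worn in the original
#'   protocol); used only for metadata and sanity checks.
#' @param sec the secondary [acc_recording()] to be corrected.
#' @param est an `alignment_estimate` for `sec` relative to `ref`.
#' @param method interpolation method, see [apply_drift_resample()];
#'   defaults to the configured method.
#' @param config an [alignment_config()].
#' @return an object of class `aligned_recording`: list with `recording`
#'   (the corrected secondary), `applied` (the estimate) and
#'   `interpolation`.
#' @export
align_pair <- function(ref, sec, est,
                       method = NULL, config = alignment_config()) {
  stopifnot(inherits(ref, "acc_recording"), inherits(sec, "acc_recording"),
            inherits(est, "alignment_estimate"))
  if (is.null(method)) method <- config$interp_method
  if (sec$fs != est$working_fs)
    stop("estimate working rate does not match the secondary recording")
  b0 <- est$fit$beta0
  b1 <- est$fit$beta1
  if (config$round_offset) {
    k <- round(b0); phase <- 0
  } else {
    k <- floor(b0); phase <- b0 - k
  }
  trimmed <- apply_offset(sec, k)
  corrected <- apply_drift_resample(trimmed, b1, method = method,
                                    phase = phase)
  structure(list(recording = corrected, applied = est,
                 interpolation = method),
            class = "aligned_recording")
}

#' @export
print.aligned_recording <- function(x, ...) {
  cat(sprintf("<aligned_recording> via '%s' interpolation\n", x$interpolation))
  print(x$applied)
  print(x$recording)
  invisible(x)
}

#' Estimate the alignment of a recording pair (Stages I + II)
#'
#' Runs the full estimation pipeline: resample both recordings to the
#' working rate if needed, pre-process, collect the hourly lag series, and
#' fit the drift line.
#'
#' @param ref,sec [acc_recording()]s (reference and secondary).
#' @param config an [alignment_config()].
#' @param ref_prep optional `ref_prep` element from a previous
#'   [estimate_alignment()] call on the same reference recording and config;
#'   reuses its pre-processing (useful when one reference is estimated
#'   against several secondaries, or when re-estimating after alignment).
#' @return list with `observations` (the `lag_series`), `fit` (the
#'   `drift_fit`), `estimate` (the `alignment_estimate`) and `ref_prep`
#'   (reusable reference pre-processing: `enmo`, `signal`, `start_time`).
#' @export
estimate_alignment <- function(ref, sec, config = alignment_config(),
                               ref_prep = NULL) {
  sec <- resample_recording(sec, config$working_fs)
  if (is.null(ref_prep)) {
    ref <- resample_recording(ref, config$working_fs)
    ref_enmo <- enmo(ref)
    ref_prep <- list(enmo = ref_enmo,
                     signal = preprocess_stage1(ref, config,
                                                enmo_values = ref_enmo),
                     start_time = ref$start_time)
  }
  sec_enmo <- enmo(sec)
  sec_sig <- preprocess_stage1(sec, config, enmo_values = sec_enmo)
  shift <- round((ref_prep$start_time - sec$start_time) * config$working_fs)
  obs <- collect_lag_series(ref_prep$signal, sec_sig, ref_prep$enmo,
                            sec_enmo, config, sec_shift_samples = shift)
  fit <- fit_drift(obs, config)
  list(observations = obs, fit = fit,
       estimate = to_alignment_estimate(fit, config$working_fs),
       ref_prep = ref_prep)
}
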