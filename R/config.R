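#' Pipeline configuration
#'
#' Collects every tunable constant of the alignment pipeline in one list.
#' Defaults are the method's published operating point: 30 Hz working rate,
#' 0.068 g dead-band, 0.1-7 Hz 4th-order zero-phase Butterworth band-pass,
#' 1-hour blocks gated at 0.01 g mean |ENMO|, and a +-1000-sample (33.3 s)
#' cross-correlation search window.
#'
#' @param working_fs working sampling rate, Hz.
#' @param deadband_g dead-band noise floor, g.
#' @param bp_low_hz,bp_high_hz band-pass edges, Hz.
#' @param bp_order total band-pass order (even).
#' @param block_s block length for lag estimation, seconds.
#' @param activity_gate_g strict lower bound on a block's mean |ENMO|, g.
#' @param max_lag_samples half-width of the lag search window, samples.
#' @param min_peak_corr optional peak-quality gate; observations whose peak
#'   correlation falls below this are dropped (0 = off; the robust fit is the
#'   primary outlier defence).
#' @param residual_mode `"standard"` (residual / residual SD) or
#'   `"studentized"` (additionally deflated by leverage) for outlier scoring.
#' @param threshold_sequence explicit numeric vector of per-iteration
#'   exclusion thresholds, or `NULL` (default) for the recurrence
#'   `t_0 = 1, t_{k+1} = exp(t_k)` (1, 2.72, 15.2, ...).
#' @param exclusion_mode `"batch"` drops every point beyond the threshold per
#'   iteration; `"single"` drops only the worst one.
#' @param interp_method Stage III resampling method: `"previous"`, `"linear"`
#'   or `"cubic"`.
#' @param round_offset if `TRUE`, Stage III trims by `round(beta0)` and
#'   ignores the fractional sample; if `FALSE` (default) it trims by
#'   `floor(beta0)` and folds the fraction into the resampling phase.
#' @param wav_scale raw-to-g factor for int16 WAV files.
#' @param manual_review_s absolute accumulated day-7 drift (s) above which a
#'   recording pair is flagged for manual review.  Default 24, the worst-case
#'   relative drift of two in-spec +-20 ppm clocks.
#' @param strict_mode convenience switch: `TRUE` sets `round_offset = TRUE`,
#'   `residual_mode = "standard"` and `exclusion_mode = "batch"`, disabling
#'   every documented refinement of the original three-stage procedure.
#' @return a named list of class `alignment_config`.
#' @export
alignment_config <- function(working_fs = 30,
                             deadband_g = 0.068,
                             bp_low_hz = 0.1,
                             bp_high_hz = 7,
                             bp_order = 4,
                             block_s = 3600,
                             activity_gate_g = 0.01,
                             max_lag_samples = 1000,
                             min_peak_corr = 0,
                             residual_mode = c("standard", "studentized"),
                             threshold_sequence = NULL,
                             exclusion_mode = c("batch", "single"),
                             interp_method = c("previous", "linear", "cubic"),
                             round_offset = FALSE,
                             wav_scale = 4096,
                             manual_review_s = 24,
                             strict_mode = FALSE) {
  cfg <- list(working_fs = working_fs, deadband_g = deadband_g,
              bp_low_hz = bp_low_hz, bp_high_hz = bp_high_hz,
              bp_order = bp_order, block_s = block_s,
              activity_gate_g = activity_gate_g,
              max_lag_samples = max_lag_samples,
              min_peak_corr = min_peak_corr,
              residual_mode = match.arg(residual_mode),
              threshold_sequence = threshold_sequence,
              exclusion_mode = match.arg(exclusion_mode),
              interp_method = match.arg(interp_method),
              round_offset = round_offset, wav_scale = wav_scale,
              manual_review_s = manual_review_s,
              strict_mode = strict_mode)
  if (strict_mode) {
    cfg$round_offset <- TRUE
    cfg$residual_mode <- "standard"
    cfg$exclusion_mode <- "batch"
  }
  stopifnot(cfg$working_fs > 0, cfg$block_s > 0, cfg$max_lag_samples >= 1,
            cfg$activity_gate_g >= 0, cfg$deadband_g >= 0)
  class(cfg) <- "alignment_config"
  cfg
}

#' Read a pipeline configuration from a YAML or key-value file
#'
#' Keys not present in the file keep their [alignment_config()] defaults.
#'
#' @param path YAML file (read with the yaml package when installed) or a
#'   flat `key: value` text file.
#' @return an [alignment_config()].
#' @export
read_config <- function(path) {
  if (requireNamespace("yaml", quietly = TRUE)) {
    vals <- yaml::read_yaml(path)
  } else {
    lines <- grep("^\\s*(#|$)", readLines(path), invert = TRUE, value = TRUE)
    kv <- strsplit(lines, "\\s*:\\s*")
    vals <- lapply(kv, function(p) utils::type.convert(p[2L], as.is = TRUE))
    names(vals) <- vapply(kv, `[[`, "", 1L)
  }
  known <- names(formals(alignment_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("config error: unknown keys: ", paste(unknown, collapse = ", "))
  do.call(alignment_config, vals)
}
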