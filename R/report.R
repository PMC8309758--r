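# Batch reporting: per-pair estimation reports, drift categories, warning
# flags, and the cohort summary used for population overviews.

#' Accumulated day-7 drift category
#'
#' Bins the absolute accumulated day-7 drift into the six standard reporting
#' categories: 0-5, >5-10, >10-15, >15-20, >20-30 and >30 s.
#'
#' @param day7_s accumulated day-7 drift in seconds (vectorized; the sign is
#'   ignored).
#' @return factor with the six category labels.
#' @export
drift_category <- function(day7_s) {
  cut(abs(day7_s), breaks = c(0, 5, 10, 15, 20, 30, Inf),
      labels = c("0-5", ">5-10", ">10-15", ">15-20", ">20-30", ">30"),
      include.lowest = TRUE, right = TRUE)
}

#' Run the estimation pipeline on a recording pair (Stages I + II)
#'
#' Accepts in-memory recordings or CSV paths, runs [estimate_alignment()],
#' and assembles a run report with the drift category and warning flags.
#' Drift beyond `config$manual_review_s` (default 24 s, the worst case two
#' in-spec clocks can produce) indicates a sampling anomaly rather than
#' ordinary clock skew and is flagged for manual review.
#'
#' @param ref,sec [acc_recording()]s or CSV file paths.
#' @param config an [alignment_config()].
#' @return an object of class `run_report`: list with `estimate`, `fit`,
#'   `observations`, `category` (character), `flags` (character vector,
#'   possibly empty: `"degenerate_fit"`, `"manual_review"`), and `config`.
#' @export
run_estimate <- function(ref, sec, config = alignment_config()) {
  if (is.character(ref)) ref <- read_acc_csv(ref)
  if (is.character(sec)) sec <- read_acc_csv(sec)
  res <- estimate_alignment(ref, sec, config)
  flags <- character()
  if (res$fit$degenerate) flags <- c(flags, "degenerate_fit")
  if (abs(res$estimate$accumulated_day7_s) > config$manual_review_s)
    flags <- c(flags, "manual_review")
  structure(list(estimate = res$estimate, fit = res$fit,
                 observations = res$observations,
                 category = as.character(drift_category(
                   res$estimate$accumulated_day7_s)),
                 flags = flags, config = config),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  print(x$estimate)
  cat(sprintf("  category %s; %d lag observations, %d excluded\n",
              x$category, nrow(x$observations), nrow(x$fit$excluded)))
  if (length(x$flags))
    cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' Writes the fit coefficients, diagnostics, exclusion record, physical-unit
#' estimates, flags and the full configuration (for provenance) as JSON.
#'
#' @param report a [run_estimate()] result.
#' @param path output path; `NULL` returns the JSON string.
#' @return `path` (or the JSON string), invisibly.
#' @export
write_report_json <- function(report, path = NULL) {
  payload <- list(
    beta0 = report$fit$beta0, beta1 = report$fit$beta1,
    rmse = report$fit$rmse, r2 = report$fit$r2,
    n_used = report$fit$n_used, iterations = report$fit$iterations,
    degenerate = report$fit$degenerate,
    excluded = report$fit$excluded,
    initial_offset_s = report$estimate$initial_offset_s,
    drift_samples_per_s = report$estimate$drift_samples_per_s,
    accumulated_day7_s = report$estimate$accumulated_day7_s,
    category = report$category, flags = as.list(report$flags),
    config = unclass(report$config))
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}

#' Write the per-block diagnostics CSV
#'
#' One row per block: gate decisions for both devices and, where estimated,
#' the lag and peak correlation.
#'
#' @param report a [run_estimate()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_block_diagnostics <- function(report, path) {
  gates <- attr(report$observations, "gates")
  obs <- as.data.frame(report$observations)
  out <- merge(gates, obs[, c("block_index", "time_s", "lag_samples",
                              "peak_corr")],
               by = "block_index", all.x = TRUE)
  data.table::fwrite(out, path)
  invisible(path)
}

#' Estimate and align a recording pair (Stages I-III)
#'
#' @param ref,sec [acc_recording()]s or CSV file paths.
#' @param config an [alignment_config()].
#' @param method interpolation method (default from config).
#' @return list with `report` (a `run_report`) and `aligned` (an
#'   `aligned_recording`).
#' @export
run_align <- function(ref, sec, config = alignment_config(), method = NULL) {
  if (is.character(ref)) ref <- read_acc_csv(ref)
  if (is.character(sec)) sec <- read_acc_csv(sec)
  report <- run_estimate(ref, sec, config)
  sec_w <- resample_recording(sec, config$working_fs)
  ref_w <- resample_recording(ref, config$working_fs)
  aligned <- align_pair(ref_w, sec_w, report$estimate, method = method,
                        config = config)
  list(report = report, aligned = aligned)
}

#' Batch estimation over a manifest of recording pairs
#'
#' Runs [run_estimate()] on every pair, tolerating partial failures, and
#' tabulates the drift-category histogram used for cohort overviews.
#'
#' @param pairs data frame with columns `ref` and `sec` (CSV paths or a list
#'   column of recordings) and optionally `id`.
#' @param config an [alignment_config()].
#' @return list with `summary` (one row per pair: id, beta0, beta1,
#'   initial_offset_s, accumulated_day7_s, category, flags, error) and
#'   `histogram` (named category counts over successful pairs).
#' @export
run_batch <- function(pairs, config = alignment_config()) {
  pairs <- as.data.frame(pairs)
  if (nrow(pairs) < 1L) stop("empty manifest: no pairs to process")
  if (is.null(pairs$id)) pairs$id <- seq_len(nrow(pairs))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    res <- tryCatch(
      run_estimate(pairs$ref[[i]], pairs$sec[[i]], config),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("pair %s failed: %s", pairs$id[[i]],
                      conditionMessage(res)), call. = FALSE)
      return(data.frame(id = as.character(pairs$id[[i]]), beta0 = NA,
                        beta1 = NA, initial_offset_s = NA,
                        accumulated_day7_s = NA, category = NA,
                        flags = "", error = conditionMessage(res)))
    }
    data.frame(id = as.character(pairs$id[[i]]), beta0 = res$fit$beta0,
               beta1 = res$fit$beta1,
               initial_offset_s = res$estimate$initial_offset_s,
               accumulated_day7_s = res$estimate$accumulated_day7_s,
               category = res$category,
               flags = paste(res$flags, collapse = ";"), error = "")
  })
  summary <- do.call(rbind, rows)
  ok <- is.na(summary$error) | summary$error == ""
  hist <- table(factor(summary$category[ok & !is.na(summary$category)],
                       levels = levels(drift_category(0))))
  list(summary = summary, histogram = hist)
}
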