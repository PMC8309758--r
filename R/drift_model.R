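# Stage II: linear lag-vs-time model with iterative standardized-residual
# outlier exclusion, plus unit conversions and the manual-marks helper.
#
# The model is lag(i) = beta1 * time(i) + beta0, with lag in samples and time
# in seconds on the reference timebase, so beta1 is the drift in samples/s
# and beta0 the initial offset in samples.  Invalid lag observations (blocks
# whose movement is not shared between wear sites) are treated as invalid
# data rather than poor estimates: they are excluded outright, iterating with
# an exponentially growing threshold on the standardized residual
# (1, e = 2.72, e^e = 15.2, ...) until an iteration excludes nothing.

# Closed-form simple OLS; returns coefficients, residual SD (sqrt(SSE/(n-2)),
# the regression "RMSE"), R^2 and leverages.  Written out explicitly so that
# stats::lm can serve as an independent oracle in tests.
ols_line <- function(x, y) {
  n <- length(x)
  xm <- mean(x); ym <- mean(y)
  sxx <- sum((x - xm)^2)
  if (sxx == 0) stop("singular design: all time points identical")
  beta1 <- sum((x - xm) * (y - ym)) / sxx
  beta0 <- ym - beta1 * xm
  res <- y - (beta0 + beta1 * x)
  sse <- sum(res^2)
  sst <- sum((y - ym)^2)
  sigma <- if (n > 2L) sqrt(sse / (n - 2L)) else 0
  list(beta0 = beta0, beta1 = beta1, residuals = res, sigma = sigma,
       r2 = if (sst > 0) 1 - sse / sst else 1,
       leverage = 1 / n + (x - xm)^2 / sxx, n = n)
}

drift_thresholds <- function(config, k) {
  seq_cfg <- config$threshold_sequence
  if (!is.null(seq_cfg)) {
    if (k <= length(seq_cfg)) return(seq_cfg[k]) else return(Inf)
  }
  t <- 1
  if (k > 1L) for (i in seq_len(k - 1L)) {
    t <- exp(t)
    if (!is.finite(t) || t > 1e12) return(Inf)
  }
  t
}

#' Fit the lag-versus-time drift line
#'
#' Ordinary least squares of `lag_samples` on `time_s`, repeated with
#' iterative outlier exclusion: at iteration k (k = 1, 2, ...) every
#' observation whose absolute standardized residual exceeds the threshold
#' t_k is dropped and the line refitted, where t_1 = 1 and
#' t_(k+1) = exp(t_k) (1, 2.72, 15.2, ...).  Iteration stops when nothing is
#' excluded, when the residuals are numerically zero (standardization is then
#' undefined), or when fewer than two points would remain (the previous fit
#' is kept and flagged `degenerate`).  Exclusions are permanent.
#'
#' @param observations a `lag_series` from [collect_lag_series()], or any
#'   data frame with columns `time_s` and `lag_samples` (an optional
#'   `block_index` column is carried into the exclusion record).
#' @param config an [alignment_config()]; uses `residual_mode`,
#'   `threshold_sequence` and `exclusion_mode`.
#' @return an object of class `drift_fit`: list with `beta0` (samples),
#'   `beta1` (samples/s), `rmse` (residual SD of the final fit, samples),
#'   `r2`, `n_used`, `iterations`, `degenerate`, and `excluded` (data frame
#'   of `block_index`, `iteration`, `std_residual`).
#' @export
fit_drift <- function(observations, config = alignment_config()) {
  x <- observations$time_s
  y <- observations$lag_samples
  n <- length(x)
  if (n < 2L) stop("fit_drift requires at least 2 observations")
  if (length(unique(x)) < 2L) stop("singular design: all time points identical")
  bidx <- if (!is.null(observations$block_index)) observations$block_index
          else seq_len(n) - 1L

  active <- rep(TRUE, n)
  excluded <- list()
  k <- 0L
  degenerate <- FALSE
  fit <- NULL
  repeat {
    fit <- ols_line(x[active], y[active])
    if (fit$sigma < 1e-12) break  # zero-residual guard
    std <- fit$residuals / fit$sigma
    if (config$residual_mode == "studentized")
      std <- std / sqrt(pmax(1 - fit$leverage, .Machine$double.eps))
    k <- k + 1L
    t_k <- drift_thresholds(config, k)
    out <- which(abs(std) > t_k)
    if (config$exclusion_mode == "single" && length(out) > 1L)
      out <- out[which.max(abs(std[out]))]
    if (length(out) == 0L) break
    if (sum(active) - length(out) < 2L) {
      degenerate <- TRUE
      break
    }
    act_idx <- which(active)[out]
    excluded[[k]] <- data.frame(block_index = bidx[act_idx], iteration = k,
                                std_residual = std[out])
    active[act_idx] <- FALSE
  }
  excl <- if (length(excluded)) do.call(rbind, excluded)
          else data.frame(block_index = integer(), iteration = integer(),
                          std_residual = numeric())
  structure(list(beta0 = fit$beta0, beta1 = fit$beta1, rmse = fit$sigma,
                 r2 = fit$r2, n_used = sum(active), iterations = k,
                 degenerate = degenerate, excluded = excl),
            class = "drift_fit")
}

#' @export
print.drift_fit <- function(x, ...) {
  cat(sprintf(
    "<drift_fit> beta0 = %.3f samples, beta1 = %.3e samples/s\n", x$beta0,
    x$beta1))
  cat(sprintf("  rmse %.4g samples, R2 %.4f, n %d (%d excluded, %d iterations)%s\n",
              x$rmse, x$r2, x$n_used, nrow(x$excluded), x$iterations,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Accumulated day-7 drift
#'
#' Converts a drift slope in samples per second into the total misalignment
#' in seconds accumulated over a 7-day recording:
#' `beta1 / fs * 86400 * 7`.
#'
#' @param beta1 drift in samples/s.
#' @param working_fs working rate in Hz (default 30).
#' @return seconds of accumulated drift at day 7.
#' @examples
#' accumulated_day7_drift(0.001)  # 20.16 s
#' @export
accumulated_day7_drift <- function(beta1, working_fs = 30) {
  beta1 / working_fs * 86400 * 7
}

#' Convert a drift fit to physical units
#'
#' @param fit a [fit_drift()] result (or any list with `beta0`/`beta1`).
#' @param working_fs working rate in Hz (default 30), used as the sampling
#'   period `1/fs` (~0.033 s/sample) for the offset and in the day-7 drift.
#' @return an object of class `alignment_estimate`: `initial_offset_s`
#'   (`beta0 / fs`), `drift_samples_per_s` (`beta1`), `accumulated_day7_s`
#'   and the underlying `fit`.
#' @export
to_alignment_estimate <- function(fit, working_fs = 30) {
  structure(list(initial_offset_s = fit$beta0 / working_fs,
                 drift_samples_per_s = fit$beta1,
                 accumulated_day7_s = accumulated_day7_drift(fit$beta1,
                                                             working_fs),
                 working_fs = working_fs, fit = fit),
            class = "alignment_estimate")
}

#' @export
print.alignment_estimate <- function(x, ...) {
  cat(sprintf("<alignment_estimate> initial offset %.3f s, drift %.3e samples/s\n",
              x$initial_offset_s, x$drift_samples_per_s))
  cat(sprintf("  accumulated day-7 drift %.3f s\n", x$accumulated_day7_s))
  invisible(x)
}

#' Alignment estimate from two manually identified offsets
#'
#' The arithmetic used with a manual (visual) reference: an offset read near
#' the start of the recording and one near the end give
#' `drift = (offset_end - offset_start) / (time_end - time_start)`,
#' `initial offset = offset_start - drift * time_start`, and the accumulated
#' day-7 drift by the same conversion as the fitted model.
#'
#' @param offset_start,offset_end manually identified offsets, samples.
#' @param time_start,time_end the corresponding time points, seconds
#'   (`time_end > time_start`).
#' @param working_fs working rate in Hz (default 30).
#' @return an `alignment_estimate` whose `fit` is a two-point pseudo-fit.
#' @export
reference_from_manual_marks <- function(offset_start, offset_end,
                                        time_start, time_end,
                                        working_fs = 30) {
  if (time_end <= time_start) stop("time_end must exceed time_start")
  drift <- (offset_end - offset_start) / (time_end - time_start)
  beta0 <- offset_start - drift * time_start
  fit <- structure(list(beta0 = beta0, beta1 = drift, rmse = 0, r2 = 1,
                        n_used = 2L, iterations = 0L, degenerate = FALSE,
                        excluded = data.frame(block_index = integer(),
                                              iteration = integer(),
                                              std_residual = numeric())),
                   class = "drift_fit")
  to_alignment_estimate(fit, working_fs)
}

# ---- closed-form RTC clock arithmetic --------------------------------------

#' Accumulated day-7 drift of a clock-skew value
#'
#' A clock running `skew_ppm` parts per million fast accumulates
#' `skew_ppm * 1e-6 * 604800` seconds of error over 7 days; two independent
#' in-spec +-20 ppm clocks can therefore drift up to ~24 s apart.
#'
#' @param skew_ppm clock frequency error in ppm.
#' @return seconds of accumulated drift after 7 days.
#' @examples
#' skew_day7_drift_s(20)  # 12.096 s
#' skew_day7_drift_s(40)  # 24.192 s, worst-case two-device spread
#' @export
skew_day7_drift_s <- function(skew_ppm) skew_ppm * 1e-6 * 7 * 86400

#' RTC skew induced by a temperature difference
#'
#' Crystal oscillators have a quadratic temperature coefficient, typically
#' about -0.04 ppm per squared degree Celsius; a 5 degC difference between
#' wear sites therefore perturbs the relative skew by only ~1 ppm, which is
#' why temperature is not modelled in the drift fit.
#'
#' @param delta_c temperature difference in degrees Celsius.
#' @param coef_ppm_per_c2 quadratic coefficient, ppm/degC^2 (default -0.04).
#' @return skew perturbation in ppm (signed; take `abs()` for the magnitude).
#' @export
temp_skew_ppm <- function(delta_c, coef_ppm_per_c2 = -0.04) {
  coef_ppm_per_c2 * delta_c^2
}

#' Duration of the cross-correlation search window
#'
#' @param max_lag_samples half-width of the lag window, samples.
#' @param working_fs working rate, Hz.
#' @return window half-width in seconds (1000 samples at 30 Hz = 33.3 s).
#' @export
max_lag_window_s <- function(max_lag_samples = 1000, working_fs = 30) {
  max_lag_samples / working_fs
}
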