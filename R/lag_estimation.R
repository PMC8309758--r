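# Stage I block processing: hourly blocks, activity gating, and per-block lag
# by coefficient-normalized cross-correlation.
#
# Sign convention (fixed package-wide): a POSITIVE lag means the secondary
# signal's events occur LATER in its stream than in the reference, i.e.
# sec[i] ~ ref[i - lag]; the secondary must be shifted backwards by `lag`
# samples to align.  The synthetic generator's ground truth and Stage III both
# use this convention.

#' Partition a signal into non-overlapping blocks
#'
#' Consecutive blocks of `block_s` seconds anchored at the start of the
#' signal; a trailing partial block is dropped.
#'
#' @param sig an [acc_signal()] or numeric vector.
#' @param block_s block length in seconds (default 3600).
#' @param fs sampling rate, taken from `sig` when it is an `acc_signal`.
#' @return list of numeric vectors (possibly empty when the signal is shorter
#'   than one block).
#' @export
partition_blocks <- function(sig, block_s = 3600, fs = NULL) {
  if (inherits(sig, "acc_signal")) {
    fs <- sig$fs
    sig <- sig$values
  }
  if (is.null(fs)) stop("fs required when sig is a plain vector")
  len <- as.integer(round(block_s * fs))
  n_blocks <- length(sig) %/% len
  if (n_blocks == 0L) return(list())
  lapply(seq_len(n_blocks) - 1L,
         function(i) sig[(i * len + 1L):((i + 1L) * len)])
}

#' Hourly activity gate
#'
#' A block participates in lag estimation only when its average movement,
#' the mean of the absolute per-sample ENMO (raw: before dead-banding and
#' filtering), strictly exceeds the gate.
#'
#' @param block_enmo numeric vector of raw per-sample ENMO values for one
#'   block.
#' @param threshold gate in g (default 0.01).  The comparison is strict
#'   (`> threshold`): a block sitting exactly at the gate is rejected.
#' @return logical scalar.
#' @export
block_is_active <- function(block_enmo, threshold = 0.01) {
  if (length(block_enmo) == 0L) stop("empty block")
  mean(abs(block_enmo)) > threshold
}

#' Coefficient-normalized cross-correlogram
#'
#' Cross-correlation of two equal-length signals over an integer lag window,
#' normalized globally by `sqrt(sum(ref^2) * sum(sec^2))` so that identical
#' signals give a peak of exactly 1 at lag 0 (the `xcorr(..., 'coeff')`
#' normalization).  Computed via FFT with sufficient zero padding to make the
#' windowed portion of the circular correlation exactly linear.
#'
#' @param ref,sec numeric vectors of equal length.
#' @param max_lag half-width of the lag window in samples.
#' @return data frame with columns `lag` (`-max_lag:max_lag`) and `value`;
#'   `value[lag = k]` is the normalized `sum(ref[i] * sec[i + k])`.  Returns
#'   `NULL` when either signal has zero energy (correlation undefined).
#' @export
xcorr_coeff <- function(ref, sec, max_lag = 1000) {
  n <- length(ref)
  if (length(sec) != n) stop("ref and sec blocks must have equal length")
  if (max_lag >= n) stop("max_lag must be smaller than the block length")
  e_ref <- sum(ref^2)
  e_sec <- sum(sec^2)
  if (e_ref == 0 || e_sec == 0) return(NULL)
  m <- stats::nextn(n + max_lag, factors = c(2, 3, 5))
  fr <- stats::fft(c(ref, numeric(m - n)))
  fx <- stats::fft(c(sec, numeric(m - n)))
  cc <- Re(stats::fft(Conj(fr) * fx, inverse = TRUE)) / m
  lags <- (-max_lag):max_lag
  idx <- ifelse(lags >= 0L, lags + 1L, m + lags + 1L)
  data.frame(lag = lags, value = cc[idx] / sqrt(e_ref * e_sec))
}

#' Per-block lag estimate
#'
#' Locates the maximum of the normalized correlogram within the lag window.
#' When several lags tie for the maximum, the lag of smallest absolute value
#' is chosen (drift is near zero early in a recording, so small lags are the
#' safer prior); a remaining tie resolves to the negative lag.  Tie-breaking
#' is flagged in the result.
#'
#' @param ref_block,sec_block equal-length preprocessed signal blocks.
#' @param max_lag half-width of the search window, samples (default 1000).
#' @return list with `lag_samples` (integer), `peak_corr` and `tie`
#'   (logical), or `NULL` when either block has zero energy.
#' @export
estimate_block_lag <- function(ref_block, sec_block, max_lag = 1000) {
  cg <- xcorr_coeff(ref_block, sec_block, max_lag)
  if (is.null(cg)) return(NULL)
  peak <- max(cg$value)
  # ties within FFT round-off count as exact
  cand <- cg$lag[cg$value >= peak - 1e-12]
  tie <- length(cand) > 1L
  if (tie) {
    cand <- cand[abs(cand) == min(abs(cand))]
    cand <- min(cand)  # prefer the negative lag on a +-k tie
  }
  list(lag_samples = as.integer(cand), peak_corr = peak, tie = tie)
}

#' Collect the hourly lag series for a recording pair
#'
#' Cuts both preprocessed signals into `block_s` blocks on the nominal shared
#' timebase, gates each block on raw mean |ENMO| in BOTH devices (a
#' cross-correlation needs movement in both channels), and estimates one lag
#' per surviving block.  The true sub-minute misalignment between
#' index-aligned blocks is far below the search window and is absorbed by it.
#'
#' @param ref_sig,sec_sig preprocessed [acc_signal()]s (reference and
#'   secondary).
#' @param ref_enmo,sec_enmo raw per-sample ENMO vectors for the gate.
#' @param config an [alignment_config()].
#' @param sec_shift_samples integer shift applied to the secondary stream's
#'   block windows when the two recordings did not start at the same nominal
#'   wall-clock time (`round((ref_start - sec_start) * fs)`).
#' @return a `lag_series` data frame with columns `block_index` (0-based),
#'   `time_s` (block start on the reference timebase), `lag_samples`,
#'   `peak_corr`; per-block gate decisions are attached as
#'   `attr(, "gates")`.  Raises an error of class `accelalign_insufficient`
#'   when fewer than two observations survive.
#' @export
collect_lag_series <- function(ref_sig, sec_sig, ref_enmo, sec_enmo,
                               config = alignment_config(),
                               sec_shift_samples = 0L) {
  stopifnot(inherits(ref_sig, "acc_signal"), inherits(sec_sig, "acc_signal"))
  fs <- ref_sig$fs
  if (sec_sig$fs != fs) stop("signals must share the working rate")
  len <- as.integer(round(config$block_s * fs))
  shift <- as.integer(round(sec_shift_samples))
  n_ref <- length(ref_sig$values)
  n_sec <- length(sec_sig$values)
  n_blocks <- min(n_ref %/% len, (n_sec - max(0L, shift)) %/% len)
  if (n_blocks < 1L)
    stop(insufficient_condition("recording shorter than one block",
                                gates = NULL))
  gates <- data.frame(block_index = seq_len(n_blocks) - 1L,
                      active_ref = NA, active_sec = NA,
                      used = FALSE, reason = "", stringsAsFactors = FALSE)
  obs <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    i0 <- (b - 1L) * len
    ridx <- (i0 + 1L):(i0 + len)
    s0 <- i0 + shift  # secondary index of the same nominal wall-clock instant
    if (s0 < 0L || s0 + len > n_sec) {
      gates$reason[b] <- "secondary window out of range"
      next
    }
    sidx <- (s0 + 1L):(s0 + len)
    a_ref <- block_is_active(ref_enmo[ridx], config$activity_gate_g)
    a_sec <- block_is_active(sec_enmo[sidx], config$activity_gate_g)
    gates$active_ref[b] <- a_ref
    gates$active_sec[b] <- a_sec
    if (!(a_ref && a_sec)) {
      gates$reason[b] <- "below activity gate"
      next
    }
    est <- estimate_block_lag(ref_sig$values[ridx], sec_sig$values[sidx],
                              config$max_lag_samples)
    if (is.null(est)) {
      gates$reason[b] <- "zero variance after preprocessing"
      next
    }
    if (est$peak_corr < config$min_peak_corr) {
      gates$reason[b] <- "below min_peak_corr"
      next
    }
    gates$used[b] <- TRUE
    obs[[b]] <- data.frame(block_index = b - 1L,
                           time_s = (b - 1L) * config$block_s,
                           lag_samples = est$lag_samples,
                           peak_corr = est$peak_corr)
  }
  out <- do.call(rbind, obs[!vapply(obs, is.null, TRUE)])
  if (is.null(out) || nrow(out) < 2L)
    stop(insufficient_condition(
      sprintf("insufficient active blocks: %d usable of %d",
              if (is.null(out)) 0L else nrow(out), n_blocks),
      gates = gates))
  attr(out, "gates") <- gates
  class(out) <- c("lag_series", "data.frame")
  out
}

insufficient_condition <- function(msg, gates = NULL) {
  structure(class = c("accelalign_insufficient", "error", "condition"),
            list(message = msg, call = sys.call(-1L), gates = gates))
}

#' Side-peak spacing of a block correlogram
#'
#' Distance from the global correlogram peak to the nearest local maximum on
#' either side.  For blocks containing shared gait at the common 2 Hz step
#' frequency the side peaks are the correlation of one signal's steps with
#' the other's previous/next step, so the spacing approximates one step
#' period (~0.5 s).
#'
#' @param cg a correlogram from [xcorr_coeff()].
#' @param fs sampling rate in Hz used to convert lags to seconds.
#' @param rel_prominence a side peak's prominence (its height above the
#'   valley separating it from the central peak) must reach this fraction
#'   of the most prominent side peak's prominence (default 0.5).  The
#'   self-scaling gate keeps the visually dominant step-period side peaks
#'   and rejects the shallow half-period ripple that rectification
#'   superimposes on the correlogram plateau.
#' @return list with `left_s`, `right_s` (spacing to each side, `NA` when no
#'   qualifying side peak exists) and `mean_s`.
#' @export
side_peak_spacing <- function(cg, fs = 30, rel_prominence = 0.5) {
  v <- cg$value
  n <- length(v)
  i_peak <- which.max(v)
  inner <- 2:(n - 1)
  is_max <- inner[v[inner] > v[inner - 1L] & v[inner] >= v[inner + 1L]]
  is_max <- setdiff(is_max, i_peak)
  if (length(is_max) == 0L)
    return(list(left_s = NA_real_, right_s = NA_real_, mean_s = NA_real_))
  prom <- vapply(is_max, function(i) {
    valley <- if (i < i_peak) min(v[i:i_peak]) else min(v[i_peak:i])
    v[i] - valley
  }, numeric(1))
  is_max <- is_max[prom >= rel_prominence * max(prom)]
  left <- is_max[is_max < i_peak]
  right <- is_max[is_max > i_peak]
  left_s <- if (length(left)) (i_peak - max(left)) / fs else NA_real_
  right_s <- if (length(right)) (min(right) - i_peak) / fs else NA_real_
  list(left_s = left_s, right_s = right_s,
       mean_s = mean(c(left_s, right_s), na.rm = TRUE))
}
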