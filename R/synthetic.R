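# Synthetic dual-channel free-living-like recordings with a ground-truth
# real-time-clock model, so every pipeline stage is testable end to end.
#
# Clock model: the reference device samples on the ideal clock (sample n at
# true time n/fs).  The secondary device's n-th sample is taken at true time
#   C(n/fs) = (1 + skew_ppm * 1e-6) * (n/fs) + offset_s.
# An event at true time t therefore appears at reference index t*fs and at
# secondary index (t - offset_s) * fs / f, so the lag (secondary index minus
# reference index, the package's sign convention) follows
#   lag(t) ~ -skew * fs * t - offset_s * fs,
# i.e. ground truth beta1 = -skew_ppm * 1e-6 * fs and
# beta0 = -offset_s * fs (to first order in the ppm-scale skew).

#' Ground-truth clock specification
#'
#' @param skew_ppm relative clock frequency error of the secondary device in
#'   parts per million (`|skew_ppm| <= 1000`; real RTCs are ~+-20 ppm).
#' @param offset_s initial clock offset of the secondary device, seconds.
#' @return an object of class `clock_spec`.
#' @export
clock_spec <- function(skew_ppm = 0, offset_s = 0) {
  if (abs(skew_ppm) > 1000)
    stop("|skew_ppm| > 1000 is outside the sanity bound")
  structure(list(skew_ppm = skew_ppm, offset_s = offset_s),
            class = "clock_spec")
}

#' Activity script
#'
#' A list of non-overlapping, time-sorted movement segments laid over an
#' otherwise sedentary (gravity + noise) recording.
#'
#' @param segments data frame with columns `start_s`, `duration_s`, `kind`
#'   (one of `"sedentary"`, `"walk"`, `"run"`, `"unshared"`), `amplitude_g`
#'   and `step_hz`.
#' @return the validated data frame with class `activity_script`.
#' @export
activity_script <- function(segments) {
  segments <- as.data.frame(segments)
  need <- c("start_s", "duration_s", "kind", "amplitude_g", "step_hz")
  if (!all(need %in% names(segments)))
    stop("invalid script: need columns ", paste(need, collapse = ", "))
  if (!all(segments$kind %in% c("sedentary", "walk", "run", "unshared")))
    stop("invalid script: unknown segment kind")
  if (any(segments$duration_s <= 0)) stop("invalid script: empty segment")
  o <- order(segments$start_s)
  segments <- segments[o, , drop = FALSE]
  ends <- segments$start_s + segments$duration_s
  if (nrow(segments) > 1L &&
      any(segments$start_s[-1L] < ends[-nrow(segments)]))
    stop("invalid script: overlapping segments")
  rownames(segments) <- NULL
  class(segments) <- c("activity_script", "data.frame")
  segments
}

#' Default free-living-like activity script
#'
#' Three movement bouts per day (morning, midday, late afternoon), each a
#' gait-like burst; a fixed fraction of the bouts is marked `unshared`
#' (movement present in both channels but uncorrelated between them, the way
#' wrist-only activity decorrelates from the hip), which exercises the
#' outlier-exclusion path of the drift fit.
#'
#' @param days recording length in days.
#' @param bout_minutes length of each movement bout, minutes (default 10).
#' @param bout_hours hours-of-day at which bouts start (default 9, 13, 17).
#' @param unshared_every every k-th bout is unshared (default 5; 0 disables).
#' @param amplitude_g burst amplitude in g (default 0.6).
#' @param step_hz gait fundamental, Hz (default 2, the common step rate).
#' @return an [activity_script()].
#' @export
default_activity_script <- function(days, bout_minutes = 10,
                                    bout_hours = c(9, 13, 17),
                                    unshared_every = 5,
                                    amplitude_g = 0.6, step_hz = 2) {
  starts <- as.vector(outer(bout_hours * 3600 + 300,
                            (seq_len(ceiling(days)) - 1L) * 86400, `+`))
  starts <- sort(starts[starts + bout_minutes * 60 < days * 86400])
  if (length(starts) == 0L) stop("invalid script: no bout fits in `days`")
  kind <- rep("walk", length(starts))
  if (unshared_every > 0)
    kind[seq_along(starts) %% unshared_every == 0L] <- "unshared"
  activity_script(data.frame(
    start_s = starts, duration_s = bout_minutes * 60, kind = kind,
    amplitude_g = amplitude_g, step_hz = step_hz))
}

# Per-segment random parameters.  Shared components (pulse shape, timing and
# the common step-timing wander) are drawn once and evaluated by both
# channels at their own sample times; `unshared` segments get independent
# per-channel draws.  The wander is a random-walk phase on a 0.25 s control grid,
# linearly interpolated, emulating natural cadence irregularity; it is what
# makes the central correlogram peak dominate the +-0.5 s side peaks.
draw_segment_params <- function(seg, wander_sd = 0.3, wander_dt = 0.25) {
  draw_one <- function() {
    m <- max(2L, ceiling(seg$duration_s / wander_dt) + 1L)
    list(ph = stats::runif(1, 0, 2 * pi),
         kappa = stats::runif(1, 4, 6),
         freq = seg$step_hz * stats::runif(1, 0.95, 1.05),
         w_t = seg$start_s + (seq_len(m) - 1L) * wander_dt,
         w = cumsum(stats::rnorm(m, 0, wander_sd)))
  }
  p <- list(shared = draw_one(),
            sec_amp = stats::runif(1, 0.5, 0.9),
            sec_dphase = stats::rnorm(1, 0, 0.05))
  if (seg$kind == "unshared") {
    # aperiodic movement for the secondary channel: band-limited noise on an
    # 8 Hz control grid (spectrum concentrated below ~4 Hz after linear
    # interpolation), nothing like the reference channel's gait
    m2 <- max(2L, ceiling(seg$duration_s * 8) + 1L)
    p$sec_own <- list(n_t = seg$start_s + (seq_len(m2) - 1L) / 8,
                      n_v = stats::rnorm(m2))
  }
  p
}

# Unrelated movement burst for the secondary channel of an `unshared`
# segment: interpolated band-limited noise, scaled so the hourly activity
# gate still passes.
eval_unshared <- function(t, seg, par) {
  seg$amplitude_g * 0.7 * stats::approx(par$n_t, par$n_v, xout = t,
                                        rule = 2)$y
}

# Evaluate one segment's waveform at times t (true seconds); returns the
# z-axis perturbation.  A gait burst is a zero-mean train of narrow
# positive pulses (von-Mises shape, one per step): the heel-strike impact
# dominates the magnitude signal once per step period, so after
# dead-banding and rectification the correlogram peaks at multiples of
# 1/step_hz with no spurious half-period structure.  Pulse width is set by
# kappa (harmonics decay as Bessel ratios; the 4th harmonic at 8 Hz is
# already outside the 7 Hz band edge).  Randomness enters as a global time
# shift (ph), pulse-width jitter (kappa) and the common cadence wander.
eval_burst <- function(t, seg, par, dphase = 0, amp_scale = 1) {
  phase <- 2 * pi * par$freq * (t - seg$start_s) + par$ph +
    stats::approx(par$w_t, par$w, xout = t, rule = 2)$y + dphase
  pulse <- exp(par$kappa * (cos(phase) - 1))
  m <- exp(-par$kappa) * besselI(par$kappa, 0)  # period mean -> zero-mean
  seg$amplitude_g * amp_scale * (pulse - m) / (1 - m)
}

#' Generate a synthetic dual-monitor recording pair
#'
#' Builds a reference (ideal-clock) and a secondary recording of the same
#' scripted free-living activity, the secondary sampled on a skewed and
#' offset clock, plus the implied ground-truth alignment estimate in the
#' package's lag sign convention.
#'
#' Shared bouts produce correlated gait bursts (a train of heel-strike-like
#' pulses at the step frequency, with common step-timing wander,
#' channel-specific amplitude and a small channel phase jitter) riding on
#' the gravity vector.  `unshared` bouts put the gait burst in the
#' reference channel only and give the secondary an unrelated aperiodic
#' movement burst in the same hour, so both activity gates pass but the
#' block's lag estimate is invalid -- the outlier the drift fit must
#' reject.  Everything else is sedentary.  White Gaussian noise of SD `noise_g` is added per axis per
#' channel.
#'
#' @param script an [activity_script()]; default [default_activity_script()].
#' @param clock a [clock_spec()].
#' @param days recording duration in days.
#' @param fs sampling rate, Hz (default 30; 50 and 100 are accepted for
#'   testing the resampling path).
#' @param seed integer seed; all randomness is routed through it.
#' @param noise_g white-noise SD per axis, g (default 0.008, a realistic
#'   MEMS noise floor after 30 Hz resampling).
#' @param halt optional `list(at_s =, jump_s =)`: emulates a firmware
#'   sampling halt by adding `jump_s` to the secondary clock offset from
#'   true time `at_s` on (abnormal-drift scenario).
#' @return list with `ref` and `sec` ([acc_recording()]s), `truth` (an
#'   `alignment_estimate` carrying `beta0 = -offset_s * fs` and
#'   `beta1 = -skew * fs`), `clock` and `script`.
#' @export
generate_pair <- function(script = NULL, clock = clock_spec(), days = 1,
                          fs = 30, seed = 1, noise_g = 0.008, halt = NULL) {
  stopifnot(days > 0, fs %in% c(30, 50, 100))
  if (is.null(script)) script <- default_activity_script(days)
  stopifnot(inherits(script, "activity_script"), inherits(clock, "clock_spec"))
  set.seed(as.integer(seed))
  params <- lapply(seq_len(nrow(script)),
                   function(i) draw_segment_params(script[i, ]))
  f_rel <- 1 + clock$skew_ppm * 1e-6
  n <- as.integer(round(days * 86400 * fs)) + 1L

  build_channel <- function(channel) {
    i <- seq_len(n) - 1L
    if (channel == "ref") {
      a <- 0; b <- 1 / fs
    } else {
      a <- clock$offset_s; b <- f_rel / fs
    }
    t_of <- function(idx) a + b * idx  # true time of sample index (0-based)
    x <- stats::rnorm(n, 0, noise_g)
    y <- stats::rnorm(n, 0, noise_g)
    z <- 1 + stats::rnorm(n, 0, noise_g)
    for (s in seq_len(nrow(script))) {
      seg <- script[s, ]
      if (seg$kind == "sedentary") next
      par <- params[[s]]
      # a sampling halt delays everything the secondary records from at_s on
      jump <- if (channel == "sec" && !is.null(halt) &&
                  seg$start_s >= halt$at_s) halt$jump_s else 0
      # index range covered by this segment on this channel's clock
      lo <- max(0L, as.integer(ceiling((seg$start_s - a - jump) / b)))
      hi <- min(n - 1L, as.integer(floor(
        (seg$start_s + seg$duration_s - a - jump) / b)))
      if (hi < lo) next
      idx <- lo:hi
      t <- t_of(idx) + jump
      if (channel == "ref") {
        burst <- eval_burst(t, seg, par$shared)
      } else if (seg$kind == "unshared") {
        burst <- eval_unshared(t, seg, par$sec_own)
      } else {
        burst <- eval_burst(t, seg, par$shared, dphase = par$sec_dphase,
                            amp_scale = par$sec_amp)
      }
      z[idx + 1L] <- z[idx + 1L] + burst
      x[idx + 1L] <- x[idx + 1L] + 0.3 * burst
    }
    cbind(x = x, y = y, z = z)
  }

  ref <- acc_recording(build_channel("ref"), fs = fs, start_time = 0,
                       device_id = "sim-ref", wear_site = "hip",
                       validate = FALSE)
  sec <- acc_recording(build_channel("sec"), fs = fs, start_time = 0,
                       device_id = "sim-sec", wear_site = "wrist",
                       validate = FALSE)
  truth_fit <- structure(
    list(beta0 = -clock$offset_s * fs, beta1 = -clock$skew_ppm * 1e-6 * fs,
         rmse = 0, r2 = 1, n_used = 0L, iterations = 0L, degenerate = FALSE,
         excluded = data.frame(block_index = integer(),
                               iteration = integer(),
                               std_residual = numeric())),
    class = "drift_fit")
  list(ref = ref, sec = sec,
       truth = to_alignment_estimate(truth_fit, fs),
       clock = clock, script = script)
}

#' Write a deterministic suite of alignment fixtures
#'
#' Generates and writes four scenario pairs as header-dialect CSVs plus a
#' JSON manifest of ground truths: a short smoke pair, a full-length pair, an
#' outlier-heavy pair (frequent unshared bouts), and an abnormal-drift pair
#' combining a 50 ppm skew with a mid-recording 400 s sampling-halt jump (so
#' the fitted pre-halt line alone already exceeds the 24 s manual-review
#' threshold).  The same seed reproduces byte-identical files.
#'
#' @param outdir writable output directory (created if missing).
#' @param seed integer master seed.
#' @param full_days length of the non-smoke pairs, days (default 7).
#' @param smoke_minutes length of the smoke pair, minutes (default 10).
#' @return the manifest (also written to `manifest.json`), invisibly.
#' @export
write_fixture_suite <- function(outdir, seed, full_days = 7,
                                smoke_minutes = 10) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  smoke_days <- smoke_minutes / 1440
  # sub-day suites squeeze the daily bout pattern into the short duration
  make_script <- function(days, unshared_every = 5) {
    if (days >= 1)
      return(default_activity_script(days, unshared_every = unshared_every))
    default_activity_script(
      days,
      bout_hours = seq(0.05, max(0.25, days * 24 - 0.2), by = 1 / 3),
      bout_minutes = 6, unshared_every = unshared_every)
  }
  scenarios <- list(
    smoke = list(days = smoke_days, clock = clock_spec(20, 0.5),
                 script = activity_script(data.frame(
                   start_s = 30, duration_s = smoke_minutes * 60 - 60,
                   kind = "walk", amplitude_g = 0.6, step_hz = 2)),
                 halt = NULL),
    full = list(days = full_days, clock = clock_spec(20, 2),
                script = make_script(full_days), halt = NULL),
    outlier_heavy = list(days = full_days, clock = clock_spec(-15, -1),
                         script = make_script(full_days,
                                              unshared_every = 3),
                         halt = NULL),
    abnormal_drift = list(days = full_days, clock = clock_spec(50, 1),
                          script = make_script(full_days),
                          halt = list(at_s = full_days * 43200,
                                      jump_s = 400)))
  manifest <- list(seed = seed, pairs = list())
  for (nm in names(scenarios)) {
    sc <- scenarios[[nm]]
    pair <- generate_pair(script = sc$script, clock = sc$clock,
                          days = sc$days, fs = 30,
                          seed = seed + match(nm, names(scenarios)),
                          halt = sc$halt)
    ref_path <- file.path(outdir, paste0(nm, "_ref.csv"))
    sec_path <- file.path(outdir, paste0(nm, "_sec.csv"))
    write_acc_csv(pair$ref, ref_path)
    write_acc_csv(pair$sec, sec_path)
    manifest$pairs[[nm]] <- list(
      ref = basename(ref_path), sec = basename(sec_path),
      skew_ppm = sc$clock$skew_ppm, offset_s = sc$clock$offset_s,
      halt = sc$halt,
      truth = list(beta0_samples = pair$truth$fit$beta0,
                   beta1_samples_per_s = pair$truth$fit$beta1,
                   initial_offset_s = pair$truth$initial_offset_s,
                   accumulated_day7_s = pair$truth$accumulated_day7_s))
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
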