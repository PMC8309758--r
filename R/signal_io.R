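# Reading, writing and rate conversion of acceleration streams.
#
# Two plain-text CSV dialects are supported:
#   * header form: two leading lines "start_time,<epoch s>" and "fs,<Hz>",
#     then an x,y,z table (fast; the uniform timebase is implicit);
#   * timestamp form: columns timestamp,x,y,z with per-row epoch seconds or
#     ISO-8601 stamps; the rate is inferred from the median timestamp step.
# WAV carries 1-2 channels of single-channel magnitude signals (PCM int16 or
# IEEE float32), the interchange format used for visual alignment in audio
# editors.

#' Read a triaxial acceleration CSV
#'
#' @param path path to a CSV file in either the header dialect (two leading
#'   `start_time` / `fs` lines followed by x,y,z columns) or the timestamp
#'   dialect (columns `timestamp`, `x`, `y`, `z`).
#' @param dialect `"auto"` (default) sniffs the first line; `"header"` or
#'   `"timestamp"` force a dialect.
#' @param device_id,wear_site metadata attached to the returned recording.
#' @return an [acc_recording()].
#' @details In the timestamp dialect the timestamps must be strictly
#'   increasing and gap-free: any step larger than twice the nominal sampling
#'   period is a data error (the first offending gap is reported).  The
#'   header dialect trusts the declared rate.
#' @seealso [write_acc_csv()]
#' @export
read_acc_csv <- function(path, dialect = c("auto", "header", "timestamp"),
                         device_id = NULL, wear_site = "other") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (dialect == "auto")
    dialect <- if (grepl("^start_time", first)) "header" else "timestamp"
  if (is.null(device_id)) device_id <- basename(path)

  if (dialect == "header") {
    hdr <- readLines(path, n = 2L)
    if (length(hdr) < 2L || !grepl("^start_time", hdr[1L]) || !grepl("^fs", hdr[2L]))
      stop("format error: header dialect requires 'start_time' and 'fs' lines")
    start_time <- as.numeric(strsplit(hdr[1L], ",")[[1L]][2L])
    fs <- as.numeric(strsplit(hdr[2L], ",")[[1L]][2L])
    if (is.na(start_time) || is.na(fs))
      stop("format error: unparseable start_time/fs header")
    dt <- data.table::fread(path, skip = 2L)
    if (!all(c("x", "y", "z") %in% names(dt)))
      stop("format error: missing x/y/z columns")
    return(acc_recording(as.matrix(dt[, c("x", "y", "z")]), fs = fs,
                         start_time = start_time, device_id = device_id,
                         wear_site = wear_site))
  }

  dt <- data.table::fread(path)
  need <- c("timestamp", "x", "y", "z")
  if (!all(need %in% names(dt)))
    stop("format error: missing columns ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  ts <- dt$timestamp
  if (!is.numeric(ts))
    ts <- as.numeric(as.POSIXct(as.character(ts), tz = "UTC"))
  if (anyNA(ts)) stop("data error: unparseable timestamps")
  d <- diff(ts)
  if (any(d <= 0))
    stop("data error: non-monotone timestamps at row ", which(d <= 0)[1L] + 1L)
  period <- stats::median(d)
  gap <- which(d > 2 * period)
  if (length(gap))
    stop(sprintf(
      "data error: timestamp gap of %.6g s at row %d (t = %.6f), exceeds 2/fs = %.6g s",
      d[gap[1L]], gap[1L] + 1L, ts[gap[1L]], 2 * period))
  acc_recording(as.matrix(dt[, c("x", "y", "z")]), fs = 1 / period,
                start_time = ts[1L], device_id = device_id,
                wear_site = wear_site)
}

#' Write a triaxial acceleration CSV (header dialect)
#'
#' @param rec an [acc_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_acc_csv <- function(rec, path) {
  stopifnot(inherits(rec, "acc_recording"))
  con <- file(path, "w")
  writeLines(c(sprintf("start_time,%.6f", rec$start_time),
               sprintf("fs,%.10g", rec$fs)), con)
  close(con)
  data.table::fwrite(data.table::as.data.table(rec$data), path,
                     append = TRUE, col.names = TRUE)
  invisible(path)
}

# ---- minimal RIFF/WAVE I/O (PCM int16 and IEEE float32) --------------------

#' Read a stereo WAV of vector-magnitude acceleration
#'
#' Reads a 2-channel WAV file carrying one magnitude signal per channel, as
#' produced for visual alignment in audio editors, and rescales samples to g.
#'
#' @param path WAV file path (PCM 16-bit integer or IEEE float32).
#' @param scale raw-to-g scale factor: `g = raw / scale`.  Default `NULL`
#'   picks 4096 for int16 files (so +-8 g spans the integer range) and 1 for
#'   float files.
#' @return list with elements `channels` (list of two numeric vectors, g),
#'   `fs` (WAV sample rate) and `scale` (the factor applied).
#' @export
read_wav_vm <- function(path, scale = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("format error: not a RIFF file")
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("format error: not a WAVE file")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      buf <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(buf[1:2], "integer", 1L, 2L, signed = FALSE,
                               endian = "little"),
        n_channels = readBin(buf[3:4], "integer", 1L, 2L, signed = FALSE,
                             endian = "little"),
        sample_rate = readBin(buf[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(buf[15:16], "integer", 1L, 2L, signed = FALSE,
                       endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("format error: missing fmt/data chunk")
  if (fmt$n_channels != 2L)
    stop(sprintf("format error: expected a 2-channel WAV, got %d channel(s)",
                 fmt$n_channels))
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    raw_vals <- readBin(data_raw, "integer", length(data_raw) / 2L, 2L,
                        signed = TRUE, endian = "little")
    if (is.null(scale)) scale <- 4096
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    raw_vals <- readBin(data_raw, "double", length(data_raw) / 4L, 4L,
                        endian = "little")
    if (is.null(scale)) scale <- 1
  } else {
    stop("format error: only PCM int16 and IEEE float32 WAV are supported")
  }
  vals <- raw_vals / scale
  n <- length(vals) %/% 2L
  idx <- seq_len(n) * 2L
  list(channels = list(vals[idx - 1L], vals[idx]),
       fs = fmt$sample_rate, scale = scale)
}

#' Write a stereo WAV of vector-magnitude acceleration
#'
#' @param ch1,ch2 numeric vectors of equal length (g).
#' @param fs sample rate in Hz (written as an integer field).
#' @param path output path.
#' @param format `"float32"` (default, stores g directly) or `"int16"`
#'   (stores `round(g * scale)`).
#' @param scale raw-to-g factor used for `"int16"`; default 4096.
#' @return `path`, invisibly.
#' @export
write_wav_vm <- function(ch1, ch2, fs, path, format = c("float32", "int16"),
                         scale = 4096) {
  format <- match.arg(format)
  stopifnot(length(ch1) == length(ch2))
  inter <- as.vector(rbind(as.numeric(ch1), as.numeric(ch2)))
  if (format == "int16") {
    samp <- as.integer(round(inter * scale))
    if (max(abs(samp)) > 32767L) stop("int16 overflow: reduce scale")
    bytes_per <- 2L; audio_format <- 1L; bits <- 16L
  } else {
    samp <- inter
    bytes_per <- 4L; audio_format <- 3L; bits <- 32L
  }
  data_size <- length(samp) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(as.integer(audio_format), con, 2L, endian = "little")
  writeBin(2L, con, 2L, endian = "little")
  writeBin(as.integer(round(fs)), con, 4L, endian = "little")
  writeBin(as.integer(round(fs)) * 2L * bytes_per, con, 4L, endian = "little")
  writeBin(2L * bytes_per, con, 2L, endian = "little")
  writeBin(as.integer(bits), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4L, endian = "little")
  if (format == "int16") {
    writeBin(samp, con, 2L, endian = "little")
  } else {
    writeBin(samp, con, 4L, endian = "little")
  }
  invisible(path)
}

#' Resample a recording to the working rate
#'
#' Linear interpolation of each axis from the uniform source timebase onto a
#' uniform target grid, as used to bring raw 50/100 Hz downloads to the 30 Hz
#' working rate.  No anti-alias filter is applied before downsampling; plain
#' linear interpolation mirrors the common raw-download workflow and is noted
#' as a limitation for spectrally rich signals.
#'
#' @param rec an [acc_recording()].
#' @param target_fs target rate in Hz, default 30.
#' @return an [acc_recording()] at `target_fs`.  When `rec$fs == target_fs`
#'   the input is returned unchanged (exact idempotence).
#' @export
resample_recording <- function(rec, target_fs = 30) {
  stopifnot(inherits(rec, "acc_recording"), target_fs > 0)
  if (rec$fs == target_fs) return(rec)
  n <- nrow(rec$data)
  if (n < 2L) stop("cannot resample a recording with fewer than 2 samples")
  dur <- (n - 1L) / rec$fs
  n_out <- floor(dur * target_fs) + 1L
  t_src <- (seq_len(n) - 1L) / rec$fs
  t_out <- (seq_len(n_out) - 1L) / target_fs
  out <- vapply(1:3, function(j)
    stats::approx(t_src, rec$data[, j], xout = t_out)$y, numeric(n_out))
  acc_recording(out, fs = target_fs, start_time = rec$start_time,
                device_id = rec$device_id, wear_site = rec$wear_site,
                range_g = rec$range_g, validate = FALSE)
}
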