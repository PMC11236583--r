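# File interfaces: F0 tracks as two-column TSV, contours as 16-bit PCM WAV,
# schedules as BIDS-events-style TSV, epoch arrays as a raw float64 container
# with a JSON sidecar.

#' Write an F0 track as two-column TSV
#'
#' Columns `time_s` and `f0_hz`; unvoiced samples are written as `NA`.
#'
#' @param pitch A [pitch_track()].
#' @param path Output path.
#' @export
write_f0_tsv <- function(pitch, path) {
  stopifnot(inherits(pitch, "pitch_track"))
  f0 <- pitch$f0
  f0[!pitch$voiced] <- NA_real_
  utils::write.table(data.frame(time_s = pitch$times, f0_hz = f0),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an F0 track from two-column TSV
#'
#' Empty or `NA` F0 values are treated as unvoiced.
#'
#' @param path Input path.
#' @return A [pitch_track()].
#' @export
read_f0_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         na.strings = c("NA", "", "NaN"))
  pitch_track(d[[1]], d[[2]], voiced = is.finite(d[[2]]) & d[[2]] > 0)
}

#' Write a mono waveform as 16-bit PCM WAV
#'
#' Minimal RIFF/WAVE writer. The waveform is clipped to \[-1, 1\] and scaled
#' to the 16-bit integer range.
#'
#' @param wave Numeric vector in \[-1, 1\].
#' @param path Output path.
#' @param sample_rate Sampling rate in Hz.
#' @export
write_wav <- function(wave, path, sample_rate) {
  pcm <- as.integer(round(pmax(-1, pmin(1, wave)) * 32767))
  n <- length(pcm)
  data_bytes <- 2L * n
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono 16-bit PCM WAV written by [write_wav()]
#'
#' @param path Input path.
#' @return List with `wave` (numeric in \[-1, 1\]) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("read_wav: not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("read_wav: not a WAVE file")
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("read_wav: no data chunk")
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, raw(), n = size - 8))
      if (fmt[1] != 1L || fmt[2] != 1L) {
        stop("read_wav: only mono PCM supported")
      }
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = size / 2, size = 2,
                     endian = "little")
      return(list(wave = pcm / 32767, sample_rate = sample_rate))
    } else {
      invisible(readBin(con, raw(), n = size))
    }
  }
}

#' Export trial schedules as a BIDS-events-style TSV
#'
#' Long table with one row per event: `onset` (s), `duration` (s),
#' `trial_type` (event label), `condition`, `sentence_length`, `trial`,
#' `block`. Onsets are absolute if the plan has been laid out on a session
#' timeline (see [layout_session()]), otherwise trial-relative.
#'
#' @param plan A `session_plan` or list of `trial_schedule`s.
#' @param path Output path.
#' @export
write_events_tsv <- function(plan, path) {
  rows <- lapply(plan, function(s) {
    off <- if (!is.null(s$onset_s)) s$onset_s else 0
    data.frame(onset = off + s$events$onset_ms / 1000,
               duration = s$events$duration_ms / 1000,
               trial_type = s$events$label,
               condition = s$contour_condition,
               sentence_length = s$sentence_length,
               trial = if (!is.null(s$trial)) s$trial else NA_integer_,
               block = if (!is.null(s$block)) s$block else NA_integer_)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an epoch array to a float64 container with JSON sidecar
#'
#' The data cube (trials x channels x samples) is stored as little-endian
#' float64 in C order (sample fastest); the sidecar (`<path>.json`) records
#' the dimensions, sample rate, epoch start time and per-trial metadata.
#'
#' @param epochs An `epoch_set` (see [extract_epochs()]).
#' @param path Output path for the binary payload (e.g. `epochs.f64`).
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  con <- file(path, "wb")
  writeBin(as.numeric(aperm(epochs$data, c(3, 2, 1))), con,
           size = 8, endian = "little")
  close(con)
  meta <- list(dims = d, dim_names = c("trial", "channel", "sample"),
               dtype = "float64", byte_order = "little", order = "C",
               sample_rate = epochs$sample_rate, t0 = epochs$t0,
               metadata = epochs$meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an epoch array written by [write_epochs()]
#'
#' @param path Path to the binary payload.
#' @return An `epoch_set`.
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(meta$dims)
  con <- file(path, "rb")
  x <- readBin(con, numeric(), n = prod(d), size = 8, endian = "little")
  close(con)
  data <- aperm(array(x, dim = rev(d)), c(3, 2, 1))
  epoch_set(data, meta$sample_rate, meta$t0,
            meta = as.data.frame(meta$metadata))
}
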