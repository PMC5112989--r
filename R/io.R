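# Minimal mono PCM WAV reading/writing and the JSON annotation sidecar.
# (No audio-file package is part of this stack, and the format is a plain
# RIFF container, so the few dozen lines live here.)

#' Write a waveform as a 16-bit PCM mono WAV file
#'
#' @param waveform Numeric vector in `[-1, 1]` (clipped otherwise).
#' @param sample_rate Sampling rate in Hz.
#' @param path Output file.
#' @export
write_wav <- function(waveform, sample_rate, path) {
  x <- as.integer(round(pmin(pmax(waveform, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_data <- length(x) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_data), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")     # PCM, mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, size = 4, endian = "little")
  writeBin(c(2L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_data, con, size = 4, endian = "little")
  writeBin(x, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path WAV file written by [write_wav()] or compatible.
#' @return List with `waveform` (numeric in `[-1, 1]`) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAV file: ", path)
  sample_rate <- NULL; bits <- NULL; x <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only PCM mono is supported")
      sample_rate <- readBin(con, integer(), 1, size = 4, endian = "little")
      invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
      invisible(readBin(con, integer(), 1, size = 2, endian = "little"))
      bits <- readBin(con, integer(), 1, size = 2, endian = "little")
      if (bits != 16L) stop("only 16-bit PCM is supported")
    } else if (identical(id, "data")) {
      x <- readBin(con, integer(), size %/% 2L, size = 2,
                   endian = "little", signed = TRUE)
      break
    } else {
      invisible(readBin(con, raw(), size))
    }
  }
  if (is.null(x) || is.null(sample_rate)) stop("malformed WAV: ", path)
  list(waveform = x / 32767, sample_rate = sample_rate)
}

#' Write the ground-truth annotation sidecar of a recording
#'
#' JSON with the event list (kind, onset, offset, syllables), phrase-1
#' groups, phrase-2 blocks, perch temperature, OTU and seed.
#'
#' @param recording A `song_recording`.
#' @param path Output JSON file.
#' @export
write_annotation <- function(recording, path) {
  gt <- recording$ground_truth
  jsonlite::write_json(list(
    events = gt$events, groups = gt$groups, ph2_blocks = gt$ph2_blocks,
    temperature_c = recording$temperature, otu = recording$otu,
    seed = recording$seed, sample_rate = recording$sample_rate),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read an annotation sidecar
#'
#' @param path JSON file written by [write_annotation()].
#' @return List with `events`, `groups`, `ph2_blocks` data.frames plus the
#'   recording metadata.
#' @export
read_annotation <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
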