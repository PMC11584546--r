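#' Waveform container
#'
#' A mono audio signal with its sampling rate and optional identifiers.
#' Samples are dimensionless amplitudes, nominally in `[-1, 1]` after
#' normalization.
#'
#' @param samples numeric vector of finite amplitudes (non-empty).
#' @param sample_rate_hz sampling rate in Hz (> 0).
#' @param subject_id optional subject identifier.
#' @param repeat_index optional repeat number (1..3 in the standard protocol).
#' @return an object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate_hz, subject_id = NA_character_,
                     repeat_index = NA_integer_) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("waveform: 'samples' must be non-empty")
  if (!all(is.finite(samples))) stop("waveform: all samples must be finite")
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("waveform: 'sample_rate_hz' must be a single positive number")
  }
  structure(
    list(samples = samples, sample_rate_hz = sample_rate_hz,
         subject_id = subject_id, repeat_index = as.integer(repeat_index)),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s)",
              length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz))
  if (!is.na(x$subject_id)) cat(sprintf("  subject=%s", x$subject_id))
  if (!is.na(x$repeat_index)) cat(sprintf(" repeat=%d", x$repeat_index))
  cat("\n")
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w a [waveform()].
#' @return duration in seconds.
#' @export
wave_duration <- function(w) {
  stopifnot(inherits(w, "waveform"))
  length(w$samples) / w$sample_rate_hz
}

#' Write a waveform to a WAV file
#'
#' Writes canonical mono RIFF/WAVE, PCM 16-bit (default) or IEEE float32.
#'
#' @param w a [waveform()]; samples outside `[-1, 1]` are clipped for PCM.
#' @param path output file path.
#' @param bit_depth 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path, bit_depth = 16L) {
  stopifnot(inherits(w, "waveform"))
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(16L, 32L)) stop("write_wav: bit_depth must be 16 or 32")
  x <- w$samples
  fs <- as.integer(round(w$sample_rate_hz))
  n <- length(x)
  bytes_per_sample <- bit_depth %/% 8L
  data_size <- n * bytes_per_sample
  fmt_code <- if (bit_depth == 16L) 1L else 3L  # PCM vs IEEE float
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                 # channels
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(fs * bytes_per_sample, con, size = 4, endian = "little")  # byte rate
  writeBin(bytes_per_sample, con, size = 2, endian = "little")   # block align
  writeBin(bit_depth, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bit_depth == 16L) {
    pcm <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
    writeBin(pcm, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file into a waveform
#'
#' Parses canonical RIFF/WAVE with PCM 16-bit or IEEE float32 data. Stereo
#' inputs are downmixed to mono by channel averaging, with a warning.
#'
#' @param path WAV file path.
#' @param subject_id,repeat_index optional identifiers attached to the result.
#' @return a [waveform()].
#' @export
read_wav <- function(path, subject_id = NA_character_, repeat_index = NA_integer_) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("read_wav: not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("read_wav: not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) stop("read_wav: no 'data' chunk in ", path)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, "integer", 1, size = 2, endian = "little")
      n_chan <- readBin(con, "integer", 1, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (size > 16L) readBin(con, "raw", size - 16L)
      fmt <- list(code = fmt_code, channels = n_chan, fs = fs, bits = bits)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("read_wav: 'data' chunk before 'fmt ' in ", path)
      if (fmt$code == 1L && fmt$bits == 16L) {
        x <- readBin(con, "integer", size %/% 2L, size = 2, signed = TRUE,
                     endian = "little") / 32767
      } else if (fmt$code == 3L && fmt$bits == 32L) {
        x <- readBin(con, "double", size %/% 4L, size = 4, endian = "little")
      } else {
        stop("read_wav: unsupported format (code ", fmt$code, ", ",
             fmt$bits, " bit) in ", path)
      }
      if (fmt$channels > 1L) {
        warning("read_wav: downmixing ", fmt$channels, " channels to mono: ", path)
        x <- rowMeans(matrix(x, ncol = fmt$channels, byrow = TRUE))
      }
      if (length(x) == 0L) stop("read_wav: empty data chunk in ", path)
      return(waveform(x, fmt$fs, subject_id = subject_id,
                      repeat_index = repeat_index))
    } else {
      readBin(con, "raw", size + size %% 2L)  # skip unknown chunk (word-aligned)
    }
  }
}
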