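#' Construct a waveform
#'
#' A waveform is the unit of all acoustic processing: a mono real-valued signal
#' in \[-1, 1\] with its sample rate.
#'
#' @param samples Numeric vector of samples, finite, nominally in \[-1, 1\].
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `waveform` with fields `samples` and `sample_rate`.
#' @export
waveform <- function(samples, sample_rate) {
  stopifnot(is.numeric(samples), length(samples) >= 1, all(is.finite(samples)),
            is.numeric(sample_rate), sample_rate > 0)
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.2f s), peak %.3f>\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate, max(abs(x$samples))))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w A `waveform`.
#' @return Duration in seconds.
#' @export
wav_duration <- function(w) length(w$samples) / w$sample_rate

#' Write a waveform as a 16-bit PCM mono WAV file
#'
#' Samples are quantized to int16 after a clipping check; a sample with
#' magnitude above 1 is an error (the simulator normalizes peaks to <= 0.9, so
#' clipping indicates a bug upstream).
#'
#' @param w A `waveform`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  if (max(abs(w$samples)) > 1)
    stop("write_wav: samples exceed full scale; refusing to clip")
  pcm <- as.integer(round(w$samples * 32767))
  n <- length(pcm)
  sr <- as.integer(round(w$sample_rate))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(sr * 2L, con, size = 4, endian = "little")      # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Walks the RIFF chunk list for `fmt ` and `data`; only uncompressed mono
#' 16-bit files (as written by [write_wav()]) are supported.
#'
#' @param path WAV file path.
#' @return A `waveform`; samples are int16 / 32767, so a write/read round trip
#'   reproduces samples to within one quantization step.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("read_wav: not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(wave, "WAVE")) stop("read_wav: not a WAVE file: ", path)
  sr <- NULL; bits <- NULL; channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1) stop("read_wav: only PCM supported")
      channels <- fmt[2]
      sr <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (sz > 16) readBin(con, "raw", sz - 16)
    } else if (identical(id, "data")) {
      samples <- readBin(con, "integer", sz / 2, size = 2, endian = "little")
      break
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
  }
  if (is.null(sr) || is.null(samples)) stop("read_wav: missing fmt/data chunk")
  if (channels != 1 || bits != 16) stop("read_wav: only mono PCM16 supported")
  waveform(samples / 32767, sr)
}
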