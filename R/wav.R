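#' Write a mono waveform as a 16-bit PCM WAV file
#'
#' Writes canonical RIFF/WAVE with a single `fmt ` chunk (PCM, 1 channel)
#' followed by the `data` chunk. Samples are clipped to \[-1, 1\] and scaled
#' by 32767 before rounding to 16-bit integers, so a round trip is exact to
#' within one quantization step.
#'
#' @param samples numeric vector of amplitudes in \[-1, 1\].
#' @param path output file path.
#' @param sample_rate sampling rate in Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 44100L) {
  stopifnot(is.numeric(samples), length(samples) > 0)
  pcm <- as.integer(round(clamp(samples, -1, 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' Parses the RIFF chunk list, locates `fmt ` and `data`, and returns samples
#' rescaled to \[-1, 1\] (division by 32767). Only uncompressed 16-bit mono
#' PCM is supported.
#'
#' @param path WAV file path.
#' @return list with `samples` (numeric vector) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("not a RIFF/WAVE file: ", path)
  }
  sample_rate <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only mono PCM WAV is supported")
      sample_rate <- readBin(con, "integer", size = 4, endian = "little")
      readBin(con, "integer", size = 4, endian = "little")
      ba_bits <- readBin(con, "integer", n = 2, size = 2, endian = "little")
      if (ba_bits[2] != 16L) stop("only 16-bit WAV is supported")
      if (size > 16) readBin(con, "raw", n = size - 16L)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", n = size %/% 2L, size = 2,
                     endian = "little")
      samples <- pcm / 32767
    } else {
      readBin(con, "raw", n = size + (size %% 2L))
    }
    if (!is.null(sample_rate) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  list(samples = samples, sample_rate = sample_rate)
}
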