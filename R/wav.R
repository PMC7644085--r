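# Minimal RIFF/WAVE I/O for 16-bit PCM. Stereo input is averaged to mono
# with a warning; samples are returned in [-1, 1].

#' Read a PCM WAV file
#'
#' Reads uncompressed 16-bit PCM WAV audio. Multichannel files are averaged
#' to mono with a warning.
#'
#' @param path Path to a `.wav` file.
#' @return A list of class `waveform` with elements `samples` (numeric,
#'   scaled to `[-1, 1]`) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1L, size = 4L, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  rate <- NULL; n_channels <- NULL; bits <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      if (fmt != 1L) stop("only uncompressed PCM WAV is supported")
      n_channels <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      rate <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      readBin(con, "integer", 1L, size = 4L, endian = "little") # byte rate
      readBin(con, "integer", 1L, size = 2L, endian = "little") # block align
      bits <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      if (size > 16L) readBin(con, "raw", size - 16L)
    } else if (identical(id, "data")) {
      if (is.null(bits)) stop("malformed WAV: data chunk before fmt chunk")
      if (bits != 16L) stop("only 16-bit PCM WAV is supported")
      data <- readBin(con, "integer", size %/% 2L, size = 2L,
                      signed = TRUE, endian = "little")
      break
    } else {
      readBin(con, "raw", size + (size %% 2L))
    }
  }
  if (is.null(data)) stop("no data chunk found in ", path)
  x <- data / 32768
  if (n_channels > 1L) {
    warning("averaging ", n_channels, " channels to mono")
    x <- rowMeans(matrix(x, ncol = n_channels, byrow = TRUE))
  }
  waveform(x, rate)
}

#' Waveform container
#'
#' @param samples Numeric vector of pressure samples (arbitrary units).
#' @param rate Sampling rate in Hz.
#' @return An object of class `waveform`.
#' @export
waveform <- function(samples, rate) {
  if (length(samples) == 0L) stop("empty waveform")
  if (!all(is.finite(samples))) stop("waveform samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("waveform rate must be positive")
  structure(list(samples = as.numeric(samples), rate = rate),
            class = "waveform")
}

#' Write a PCM WAV file
#'
#' Writes a mono 16-bit PCM WAV file; samples are clipped to `[-1, 1]`.
#'
#' @param wav A `waveform` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wav, path) {
  stopifnot(inherits(wav, "waveform"))
  x <- pmax(pmin(wav$samples, 1), -1)
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")   # PCM
  writeBin(1L, con, size = 2L, endian = "little")   # mono
  writeBin(as.integer(wav$rate), con, size = 4L, endian = "little")
  writeBin(as.integer(wav$rate) * 2L, con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
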