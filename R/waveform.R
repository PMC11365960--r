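#' Construct a waveform object
#'
#' A waveform is the raw observable of the pipeline: a mono vector of audio
#' samples in `[-1, 1]` plus its sampling rate.
#'
#' @param samples numeric vector of audio samples.
#' @param sr sampling rate in Hz (the study recorded at 40 kHz).
#' @return an object of class `waveform` with fields `samples` and `sr`.
#' @export
waveform <- function(samples, sr) {
  stopifnot_scalar(sr, "sr", lo = 1)
  if (!is.numeric(samples)) stop("`samples` must be numeric", call. = FALSE)
  structure(list(samples = as.double(samples), sr = as.double(sr)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples, %.0f Hz, %.3f s, peak %.3f>\n",
              length(x$samples), x$sr, wave_duration(x),
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w a [waveform()].
#' @return duration in seconds.
#' @export
wave_duration <- function(w) length(w$samples) / w$sr

#' Write a mono waveform to a RIFF WAV file
#'
#' @param w a [waveform()]; samples outside `[-1, 1]` are clipped.
#' @param path output file path.
#' @param bit_depth `"pcm16"` (default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
wav_write <- function(w, path, bit_depth = c("pcm16", "float32")) {
  bit_depth <- match.arg(bit_depth)
  x <- pmin(1, pmax(-1, w$samples))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(x)
  if (bit_depth == "pcm16") {
    fmt_code <- 1L; bits <- 16L; data_bytes <- 2L * n
  } else {
    fmt_code <- 3L; bits <- 32L; data_bytes <- 4L * n
  }
  block_align <- bits %/% 8L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(w$sr), con, size = 4, endian = "little")
  writeBin(as.integer(w$sr * block_align), con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (bit_depth == "pcm16") {
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  } else {
    writeBin(as.double(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono RIFF WAV file
#'
#' Supports uncompressed 16-bit PCM and 32-bit IEEE float, the formats the
#' generator writes. Multi-channel files are rejected.
#'
#' @param path WAV file path.
#' @return a [waveform()].
#' @export
wav_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, integer(), size = 4, endian = "little")
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    stop("not a WAVE file: ", path, call. = FALSE)
  }
  fmt <- NULL; sr <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk in ", path, call. = FALSE)
    size <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), size = 2, endian = "little")
      n_chan <- readBin(con, integer(), size = 2, endian = "little")
      if (n_chan != 1L) stop("only mono WAV supported (", n_chan, " channels)", call. = FALSE)
      sr <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (size > 16L) readBin(con, raw(), n = size - 16L)
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path, call. = FALSE)
      if (fmt == 1L && bits == 16L) {
        x <- readBin(con, integer(), n = size %/% 2L, size = 2,
                     endian = "little", signed = TRUE) / 32767
      } else if (fmt == 3L && bits == 32L) {
        x <- readBin(con, double(), n = size %/% 4L, size = 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (fmt ", fmt, ", ", bits, " bit)", call. = FALSE)
      }
      return(waveform(x, sr))
    } else {
      readBin(con, raw(), n = size + (size %% 2L))
    }
  }
}
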