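#' Read a RIFF WAV file
#'
#' Reads a mono or multi-channel PCM (8/16/24/32-bit integer) or IEEE float
#' (32/64-bit) WAV file. Multi-channel audio is downmixed to mono by the
#' per-sample channel mean; samples are returned as doubles in `[-1, 1]`.
#'
#' @param path Path to a `.wav` file.
#' @param resampleTo Target sample rate in Hz, or `NULL` to keep the native
#'   rate. Resampling uses a polyphase filter ([signal::resample()]).
#' @return A list with `samples` (numeric vector in `[-1, 1]`, mono) and
#'   `sampleRate` (Hz).
#' @examples
#' f <- tempfile(fileext = ".wav")
#' writeWav(f, sin(2 * pi * 440 * seq_len(22050) / 22050), 22050)
#' w <- readWav(f)
#' w$sampleRate
#' @seealso [writeWav()]
#' @export
readWav <- function(path, resampleTo = NULL) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAV file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")      # total size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  dataRaw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        audioFormat   = .leUInt(body[1:2]),
        nChannels     = .leUInt(body[3:4]),
        sampleRate    = .leUInt(body[5:8]),
        bitsPerSample = .leUInt(body[15:16])
      )
      # WAVE_FORMAT_EXTENSIBLE: true format code sits in the SubFormat GUID
      if (fmt$audioFormat == 65534L && sz >= 40) {
        fmt$audioFormat <- .leUInt(body[25:26])
      }
    } else if (identical(id, "data")) {
      dataRaw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + (sz %% 2L))              # skip unknown chunk
      next
    }
    if (sz %% 2L == 1L) readBin(con, "raw", 1)          # chunk padding
    if (!is.null(fmt) && !is.null(dataRaw)) break
  }
  if (is.null(fmt) || is.null(dataRaw)) stop("corrupt WAV (missing fmt/data chunk): ", path)

  bytesPer <- fmt$bitsPerSample %/% 8L
  n <- length(dataRaw) %/% bytesPer
  x <- if (fmt$audioFormat == 3L) {
    if (fmt$bitsPerSample == 32L) {
      readBin(dataRaw, "double", n, size = 4, endian = "little")
    } else {
      readBin(dataRaw, "double", n, size = 8, endian = "little")
    }
  } else if (fmt$audioFormat == 1L) {
    if (fmt$bitsPerSample == 16L) {
      readBin(dataRaw, "integer", n, size = 2, signed = TRUE, endian = "little") / 32768
    } else if (fmt$bitsPerSample == 8L) {
      (readBin(dataRaw, "integer", n, size = 1, signed = FALSE) - 128) / 128
    } else if (fmt$bitsPerSample == 24L) {
      .int24ToDouble(dataRaw)
    } else if (fmt$bitsPerSample == 32L) {
      readBin(dataRaw, "integer", n, size = 4, endian = "little") / 2147483648
    } else {
      stop("unsupported PCM bit depth: ", fmt$bitsPerSample)
    }
  } else {
    stop("unsupported WAV format code: ", fmt$audioFormat)
  }

  if (fmt$nChannels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$nChannels))
  }
  sr <- fmt$sampleRate
  if (!is.null(resampleTo) && resampleTo != sr) {
    x <- resampleAudio(x, sr, resampleTo)
    sr <- as.integer(resampleTo)
  }
  list(samples = as.numeric(x), sampleRate = as.integer(sr))
}

#' Write a mono waveform to a WAV file
#'
#' Writes 16-bit PCM. Samples are clipped to `[-1, 1]` before quantization.
#'
#' @param path Output path.
#' @param samples Numeric vector of samples in `[-1, 1]`.
#' @param sampleRate Sample rate in Hz.
#' @return `path`, invisibly.
#' @export
writeWav <- function(path, samples, sampleRate) {
  stopifnot(is.numeric(samples), length(samples) > 0, sampleRate > 0)
  q <- as.integer(pmax(-32768, pmin(32767, round(pmax(-1, pmin(1, samples)) * 32767))))
  dataSize <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + dataSize, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                     # PCM
  writeBin(1L, con, size = 2, endian = "little")                     # mono
  writeBin(as.integer(sampleRate), con, size = 4, endian = "little")
  writeBin(as.integer(sampleRate) * 2L, con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")                     # block align
  writeBin(16L, con, size = 2, endian = "little")                    # bits
  writeChar("data", con, eos = NULL)
  writeBin(dataSize, con, size = 4, endian = "little")
  writeBin(q, con, size = 2, endian = "little")
  invisible(path)
}

#' Resample a waveform
#'
#' Rational-factor polyphase resampling via [signal::resample()].
#'
#' @param x Numeric waveform.
#' @param from,to Source and target sample rates in Hz.
#' @return Resampled numeric vector of length `round(length(x) * to / from)`.
#' @export
resampleAudio <- function(x, from, to) {
  if (from == to) return(x)
  g <- .gcd(as.integer(from), as.integer(to))
  p <- as.integer(to) %/% g
  q <- as.integer(from) %/% g
  y <- signal::resample(x, p, q)
  nOut <- round(length(x) * to / from)
  if (length(y) >= nOut) y[seq_len(nOut)] else c(y, numeric(nOut - length(y)))
}

.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)

.leUInt <- function(bytes) {
  sum(as.integer(bytes) * 256^(seq_along(bytes) - 1))
}

.int24ToDouble <- function(raw) {
  n <- length(raw) %/% 3L
  m <- matrix(as.integer(raw), nrow = 3L)
  v <- m[1, ] + m[2, ] * 256 + m[3, ] * 65536
  v <- ifelse(v >= 8388608, v - 16777216, v)
  v / 8388608
}
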