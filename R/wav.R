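#' Read a RIFF WAV file
#'
#' Minimal reader for uncompressed WAV: PCM 16/24-bit and IEEE float32,
#' any channel count (the package uses mono and stereo at 44.1 kHz).
#'
#' @param path file path.
#' @param calibration dB SPL of a full-scale sinusoid to attach.
#' @return an [audio_signal].
#' @export
read_wav <- function(path, calibration = 100) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (hdr != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 4, useBytes = TRUE) != "WAVE") stop("not a WAVE file")
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = sum(as.integer(raw[1:2]) * c(1, 256)),
        channels = sum(as.integer(raw[3:4]) * c(1, 256)),
        rate = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(raw[15:16]) * c(1, 256))
      )
    } else if (id == "data") {
      data <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("missing fmt or data chunk")
  x <- if (fmt$audio_format == 3 && fmt$bits == 32) {
    readBin(data, "numeric", length(data) / 4, 4, endian = "little")
  } else if (fmt$audio_format == 1 && fmt$bits == 16) {
    readBin(data, "integer", length(data) / 2, 2, signed = TRUE,
            endian = "little") / 32768
  } else if (fmt$audio_format == 1 && fmt$bits == 24) {
    n <- length(data) / 3
    b <- matrix(as.integer(data), 3, n)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v[v >= 2^23] <- v[v >= 2^23] - 2^24
    v / 2^23
  } else stop("unsupported WAV format (PCM 16/24 and float32 only)")
  audio_signal(matrix(x, ncol = fmt$channels, byrow = TRUE),
               rate = fmt$rate, calibration = calibration)
}

#' Write an audio signal as a RIFF WAV file
#'
#' @param x an [audio_signal].
#' @param path output path.
#' @param bits 16 or 24 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, bits = 16) {
  if (!bits %in% c(16, 24, 32)) stop("bits must be 16, 24 or 32")
  s <- t(x$samples)                      # interleave channels
  v <- as.numeric(s)
  nch <- n_channels(x)
  fmt_code <- if (bits == 32) 3L else 1L
  bytes_per <- bits / 8
  data_size <- length(v) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(as.integer(nch), con, 2, endian = "little")
  writeBin(as.integer(x$rate), con, 4, endian = "little")
  writeBin(as.integer(x$rate * nch * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(nch * bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 32) {
    writeBin(v, con, 4, endian = "little")
  } else {
    vc <- pmax(-1, pmin(1, v))
    if (bits == 16) {
      writeBin(as.integer(round(vc * 32767)), con, 2, endian = "little")
    } else {
      iv <- round(vc * (2^23 - 1))
      iv[iv < 0] <- iv[iv < 0] + 2^24
      b <- rbind(iv %% 256, (iv %/% 256) %% 256, iv %/% 65536)
      writeBin(as.raw(b), con)
    }
  }
  invisible(path)
}
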