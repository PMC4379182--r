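# Minimal RIFF/WAVE reader and writer for mono analysis work: 16- and
# 24-bit integer PCM and 32-bit IEEE float, implemented directly with
# readBin/writeBin since the analysis only needs plain sample access.

#' Read a WAV file
#'
#' Supports uncompressed PCM (16 or 24 bit) and 32-bit IEEE-float RIFF/WAVE
#' files, including the WAVE_FORMAT_EXTENSIBLE wrapper. Multi-channel files
#' are mixed down to mono by channel averaging, with a warning. Samples are
#' returned as doubles in [-1, 1] (integer formats are scaled by their full
#' range).
#'
#' @param path file path.
#' @return List with \code{samples} (numeric vector) and \code{sample_rate}
#'   (Hz).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file", call. = FALSE)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file", call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        format = sum(as.integer(raw[1:2]) * c(1, 256)),
        channels = sum(as.integer(raw[3:4]) * c(1, 256)),
        sample_rate = sum(as.integer(raw[5:8]) * c(1, 256, 65536, 16777216)),
        bits = sum(as.integer(raw[15:16]) * c(1, 256)))
      if (fmt$format == 65534L && size >= 40L)   # extensible: subformat tag
        fmt$format <- sum(as.integer(raw[25:26]) * c(1, 256))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2L == 1L) readBin(con, "raw", 1)    # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("missing fmt or data chunk", call. = FALSE)
  x <- switch(as.character(fmt$format),
    "1" = {
      if (fmt$bits == 16L) {
        readBin(data_raw, "integer", length(data_raw) / 2L, 2,
                signed = TRUE, endian = "little") / 32768
      } else if (fmt$bits == 24L) {
        n <- length(data_raw) %/% 3L
        b <- matrix(as.integer(data_raw[seq_len(3L * n)]), nrow = 3L)
        v <- b[1L, ] + 256 * b[2L, ] + 65536 * b[3L, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      } else stop("unsupported PCM bit depth: ", fmt$bits, call. = FALSE)
    },
    "3" = readBin(data_raw, "double", length(data_raw) / 4L, 4,
                  endian = "little"),
    stop("unsupported WAV encoding (format tag ", fmt$format, ")",
         call. = FALSE))
  if (fmt$channels > 1L) {
    warning("mixing ", fmt$channels, " channels down to mono")
    n <- length(x) %/% fmt$channels
    x <- rowMeans(matrix(x[seq_len(n * fmt$channels)], ncol = fmt$channels,
                         byrow = TRUE))
  }
  list(samples = x, sample_rate = fmt$sample_rate)
}

#' Write a WAV file
#'
#' Writes a mono waveform as 32-bit IEEE float (lossless round trip,
#' default) or 16-bit PCM (samples clipped to [-1, 1] and quantized).
#'
#' @param path file path.
#' @param samples numeric vector.
#' @param sample_rate sampling frequency in Hz.
#' @param bits \code{"float32"} or \code{"16"}.
#' @return The path, invisibly.
#' @export
write_wav <- function(path, samples, sample_rate, bits = c("float32", "16")) {
  bits <- match.arg(bits)
  check_scalar(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  samples <- as.numeric(samples)
  con <- file(path, "wb")
  on.exit(close(con))
  bytes_per <- if (bits == "float32") 4L else 2L
  fmt_tag <- if (bits == "float32") 3L else 1L
  data_size <- length(samples) * bytes_per
  w32 <- function(x) writeBin(as.integer(x), con, 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, 2, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w32(36L + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16L); w16(fmt_tag); w16(1L)                  # mono
  w32(as.integer(sample_rate))
  w32(as.integer(sample_rate) * bytes_per)         # byte rate
  w16(bytes_per); w16(8L * bytes_per)
  writeChar("data", con, eos = NULL)
  w32(data_size)
  if (bits == "float32") {
    writeBin(samples, con, 4, endian = "little")
  } else {
    q <- round(pmax(pmin(samples, 1), -1) * 32767)
    writeBin(as.integer(q), con, 2, endian = "little")
  }
  invisible(path)
}
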