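# Minimal RIFF/WAVE reader and writer (PCM 16-bit and IEEE float32, mono or
# multi-channel). Only the fmt and data chunks are interpreted; other chunks
# are skipped. Multi-channel files yield channel 1 with a warning.

#' Read a WAV file as a PCG signal
#'
#' Supports PCM 8/16/24/32-bit integer and 32/64-bit IEEE float encodings.
#' Multi-channel files are reduced to the first channel (with a warning).
#' Integer samples are scaled to `[-1, 1)` by the full scale of the bit depth
#' (e.g. 16384 in a 16-bit file reads as 0.5).
#'
#' @param path Path to a `.wav` file.
#' @return A [pcg_signal] at the file's native sampling rate.
#' @export
load_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        format   = readBin(fmt_raw[1:2], "integer", 1L, 2L, endian = "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1L, 2L, endian = "little"),
        rate     = readBin(fmt_raw[5:8], "integer", 1L, 4L, endian = "little"),
        bits     = readBin(fmt_raw[15:16], "integer", 1L, 2L, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("corrupt WAV (missing fmt or data chunk): ", path, call. = FALSE)
  }
  if (fmt$format == 65534L) fmt$format <- if (fmt$bits >= 32L) 3L else 1L

  bytes <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes
  if (n_total == 0L) stop("empty WAV file: ", path, call. = FALSE)

  x <- if (fmt$format == 3L) {
    readBin(data_raw, "double", n_total, size = bytes, endian = "little")
  } else if (fmt$format == 1L && fmt$bits == 8L) {
    # 8-bit PCM is unsigned
    (readBin(data_raw, "integer", n_total, size = 1L, signed = FALSE) - 128) / 128
  } else if (fmt$format == 1L && fmt$bits == 24L) {
    m <- matrix(as.integer(data_raw), nrow = 3L)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    ifelse(v >= 8388608, v - 16777216, v) / 8388608
  } else if (fmt$format == 1L) {
    readBin(data_raw, "integer", n_total, size = bytes, signed = TRUE,
            endian = "little") / 2^(fmt$bits - 1L)
  } else {
    stop("unsupported WAV encoding (format tag ", fmt$format, ")", call. = FALSE)
  }

  if (fmt$channels > 1L) {
    warning("multi-channel WAV: using channel 1 of ", fmt$channels, call. = FALSE)
    x <- x[seq(1L, length(x), by = fmt$channels)]
  }
  if (!length(x)) stop("empty WAV file: ", path, call. = FALSE)
  pcg_signal(x, fmt$rate, source_id = basename(path))
}

#' Write a PCG signal to a WAV file
#'
#' @param signal A [pcg_signal].
#' @param path Output path.
#' @param bits 16 (PCM integer, default) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, bits = 16L) {
  stopifnot(inherits(signal, "pcg_signal"), bits %in% c(16L, 32L))
  x <- signal$samples
  n <- length(x)
  data_size <- n * (bits %/% 8L)
  fmt_tag <- if (bits == 32L) 3L else 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(as.integer(fmt_tag), con, size = 2L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(as.integer(round(signal$rate)), con, size = 4L, endian = "little")
  writeBin(as.integer(round(signal$rate) * (bits %/% 8L)), con, size = 4L,
           endian = "little")
  writeBin(as.integer(bits %/% 8L), con, size = 2L, endian = "little")
  writeBin(as.integer(bits), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (bits == 32L) {
    writeBin(x, con, size = 4L, endian = "little")
  } else {
    q <- as.integer(pmax(-32768, pmin(32767, round(x * 32768))))
    writeBin(q, con, size = 2L, endian = "little")
  }
  invisible(path)
}
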