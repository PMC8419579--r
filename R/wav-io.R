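# Minimal RIFF/WAVE PCM I/O (mono or interleaved multi-channel, 16/24/32 bit).
# The installed stack ships no WAV codec for R, and PCM WAV is simple enough
# that a direct reader/writer is the smallest dependency surface.

#' Write a waveform to a PCM WAV file
#'
#' Writes mono linear PCM (little-endian). Samples are clipped to \[-1, 1\].
#'
#' @param x A [Waveform-class].
#' @param path Output file path.
#' @param bits Bit depth: 16, 24 or 32.
#' @return `path`, invisibly.
#' @export
writeWav <- function(x, path, bits = 16L) {
  stopifnot(is(x, "Waveform"))
  bits <- as.integer(bits)
  if (!bits %in% c(16L, 24L, 32L)) stop("bits must be 16, 24 or 32")
  rate <- as.integer(round(x@rate))
  n <- length(x@samples)
  bytes_per <- bits %/% 8L
  block_align <- bytes_per            # mono
  data_size <- n * bytes_per
  s <- pmin(1, pmax(-1, x@samples))
  full <- 2^(bits - 1)
  q <- as.integer(round(s * (full - 1)))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # channels
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * block_align, con, size = 4, endian = "little")
  writeBin(block_align, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16L) {
    writeBin(q, con, size = 2, endian = "little")
  } else if (bits == 24L) {
    u <- ifelse(q < 0, q + 16777216, q)    # two's complement, 3 bytes
    raw3 <- as.raw(rbind(u %% 256L, (u %/% 256L) %% 256L, (u %/% 65536L) %% 256L))
    writeBin(raw3, con)
  } else {
    writeBin(q, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a PCM WAV file
#'
#' Reads linear PCM RIFF/WAVE (16/24/32 bit). Multi-channel files are
#' mixed down by averaging channels.
#'
#' @param path Input WAV path.
#' @return A [Waveform-class] with amplitudes in \[-1, 1\].
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, "integer", size = 2, endian = "little"),
        channels = readBin(con, "integer", size = 2, endian = "little"),
        rate = readBin(con, "integer", size = 4, endian = "little"),
        byte_rate = readBin(con, "integer", size = 4, endian = "little"),
        block_align = readBin(con, "integer", size = 2, endian = "little"),
        bits = readBin(con, "integer", size = 2, endian = "little")
      )
      if (size > 16) invisible(readBin(con, "raw", n = size - 16))
    } else if (id == "data") {
      dat <- readBin(con, "raw", n = size)
      break
    } else {
      invisible(readBin(con, "raw", n = size + size %% 2L))
    }
  }
  if (is.null(fmt) || is.null(dat)) stop("missing fmt/data chunk in ", path)
  if (fmt$audio_format != 1L) stop("only linear PCM WAV is supported")
  bits <- fmt$bits
  full <- 2^(bits - 1)
  x <- switch(as.character(bits),
    "16" = readBin(dat, "integer", n = length(dat) %/% 2L, size = 2,
                   signed = TRUE, endian = "little"),
    "24" = {
      m <- matrix(as.integer(dat), nrow = 3)
      v <- m[1, ] + 256L * m[2, ] + 65536L * m[3, ]
      ifelse(v >= 8388608, v - 16777216, v)
    },
    "32" = readBin(dat, "integer", n = length(dat) %/% 4L, size = 4,
                   endian = "little"),
    stop("unsupported bit depth: ", bits)
  )
  if (fmt$channels > 1L) {
    nfr <- length(x) %/% fmt$channels
    x <- colMeans(matrix(x[seq_len(nfr * fmt$channels)], nrow = fmt$channels))
  }
  waveform(x / full, fmt$rate)
}
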