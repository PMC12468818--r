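#' Read a RIFF/WAVE PCM file
#'
#' Reads 16-bit PCM (and 8/32-bit integer PCM) WAV files. Samples are scaled
#' to `[-1, 1]`. Multichannel files are returned with one channel per row of a
#' matrix; use [to_mono()] to collapse them.
#'
#' @param path Path to a `.wav` file.
#' @return A [waveform()] object. For multichannel input, `samples` is a
#'   `channels x n` matrix.
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) {
    stop("WAV file not found: ", path, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("Not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("Not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = .le_u16(body[1:2]),
        n_channels   = .le_u16(body[3:4]),
        sample_rate  = .le_u32(body[5:8]),
        bits         = .le_u16(body[15:16])
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size)
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)  # chunk padding byte
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("Malformed WAV (missing fmt or data chunk): ", path, call. = FALSE)
  }
  if (fmt$audio_format != 1L) {
    stop("Only PCM WAV is supported (format tag ", fmt$audio_format, "): ",
         path, call. = FALSE)
  }

  bytes <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes
  x <- switch(as.character(fmt$bits),
    "8"  = (as.numeric(readBin(data_raw, "integer", n_total, size = 1,
                               signed = FALSE)) - 128) / 128,
    "16" = readBin(data_raw, "integer", n_total, size = 2, signed = TRUE,
                   endian = "little") / 32767,
    "32" = readBin(data_raw, "integer", n_total, size = 4,
                   endian = "little") / 2147483648,
    stop("Unsupported PCM bit depth: ", fmt$bits, call. = FALSE)
  )
  nc <- fmt$n_channels
  if (nc > 1L) {
    x <- matrix(x, nrow = nc)  # samples are interleaved by channel
  }
  waveform(x, fmt$sample_rate)
}

#' Write a waveform as 16-bit PCM mono WAV
#'
#' Samples are clipped to `[-1, 1]` and quantized to 16-bit PCM.
#'
#' @param w A mono [waveform()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  w <- as_waveform(w)
  if (is.matrix(w$samples)) stop("write_wav() expects mono audio", call. = FALSE)
  x <- pmin(1, pmax(-1, w$samples))
  pcm <- as.integer(round(x * 32767))

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("Cannot open for writing: ", path,
                                           call. = FALSE))
  on.exit(close(con))
  n <- length(pcm)
  data_size <- 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                    # PCM
  writeBin(1L, con, size = 2, endian = "little")                    # mono
  writeBin(as.integer(w$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")                    # block align
  writeBin(16L, con, size = 2, endian = "little")                   # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

.le_u16 <- function(b) as.integer(b[1]) + 256L * as.integer(b[2])
.le_u32 <- function(b) {
  as.numeric(b[1]) + 256 * as.numeric(b[2]) +
    65536 * as.numeric(b[3]) + 16777216 * as.numeric(b[4])
}
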