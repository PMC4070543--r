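# Minimal RIFF/WAVE codec for 16-bit PCM mono files. ENVIRONMENT-independent:
# implemented directly on readBin/writeBin (little-endian throughout).

#' Read a mono 16-bit PCM WAV file
#'
#' Parses the RIFF container, locates the `fmt ` and `data` chunks and returns
#' the samples rescaled to `[-1, 1]`. Only uncompressed 16-bit PCM mono audio
#' is supported; anything else is an error rather than a silent conversion.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector in `[-1, 1]`) and
#'   `sample_rate` (Hz), the `audio_signal` structure consumed by
#'   [extract_features()].
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_invalid("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop_invalid("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1, 256)),
        channels     = sum(as.integer(body[3:4]) * c(1, 256)),
        sample_rate  = sum(as.integer(body[5:8]) * c(1, 256, 65536, 16777216)),
        bits         = sum(as.integer(body[15:16]) * c(1, 256))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop_invalid("missing fmt/data chunk in ", path)
  }
  if (fmt$audio_format != 1L || fmt$bits != 16L) {
    stop_invalid("only 16-bit PCM WAV is supported (got format ",
                 fmt$audio_format, ", ", fmt$bits, " bits)")
  }
  if (fmt$channels != 1L) {
    stop_invalid("only mono WAV is supported (got ", fmt$channels, " channels)")
  }
  pcm <- readBin(data_raw, "integer", n = length(data_raw) / 2,
                 size = 2, signed = TRUE, endian = "little")
  list(samples = pcm / 32768, sample_rate = fmt$sample_rate)
}

#' Write a mono 16-bit PCM WAV file
#'
#' Samples outside `[-1, 1]` are clipped before quantisation to 16 bits.
#'
#' @param samples Numeric vector of amplitudes, nominally in `[-1, 1]`.
#' @param sample_rate Sampling rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path) {
  stopifnot(is.numeric(samples), length(samples) > 0, sample_rate > 0)
  pcm <- as.integer(pmax(-32768, pmin(32767, round(samples * 32768))))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                  # PCM
  writeBin(1L, con, size = 2, endian = "little")                  # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")                  # block align
  writeBin(16L, con, size = 2, endian = "little")                 # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
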