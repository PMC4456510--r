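# Minimal mono RIFF/WAVE reader and writer (16-bit PCM or 32-bit float).
# Kept deliberately small: courtship recordings are single-channel and
# uncompressed, so the full format zoo is out of scope.

#' Write an audio trace to a WAV file
#'
#' @param trace an `audio_trace` (or list with `samples`, `rate`).
#' @param path output file path.
#' @param format `"float"` (32-bit IEEE) or `"pcm16"`; PCM clips at +/-1.
#' @return `path`, invisibly.
#' @export
write_wav <- function(trace, path, format = c("float", "pcm16")) {
  format <- match.arg(format)
  x <- trace$samples
  rate <- as.integer(trace$rate)
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "float") {
    fmt_code <- 3L; bits <- 32L
    payload <- function() writeBin(as.numeric(x), con, size = 4,
                                   endian = "little")
  } else {
    fmt_code <- 1L; bits <- 16L
    q <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
    payload <- function() writeBin(q, con, size = 2, endian = "little")
  }
  bytes_per_sample <- bits %/% 8L
  data_len <- length(x) * bytes_per_sample
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_len), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(rate, con, size = 4, endian = "little")
  writeBin(rate * bytes_per_sample, con, size = 4, endian = "little")
  writeBin(bytes_per_sample, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  payload()
  invisible(path)
}

#' Read a mono WAV file
#'
#' @param path WAV file (mono, 16-bit PCM or 32-bit float).
#' @return An `audio_trace`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fmt_code <- NULL; rate <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || nchar(id) < 4) break
    len <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      channels <- readBin(con, integer(), size = 2, endian = "little")
      rate <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (channels != 1) stop("only mono WAV files are supported")
      if (len > 16) invisible(readBin(con, raw(), n = len - 16))
    } else if (id == "data") {
      if (is.null(fmt_code)) stop("malformed WAV: data before fmt chunk")
      if (fmt_code == 3 && bits == 32) {
        samples <- readBin(con, numeric(), n = len / 4, size = 4,
                           endian = "little")
      } else if (fmt_code == 1 && bits == 16) {
        samples <- readBin(con, integer(), n = len / 2, size = 2,
                           endian = "little") / 32767
      } else stop("unsupported WAV encoding (need float32 or PCM16)")
      break
    } else {
      invisible(readBin(con, raw(), n = len))
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  audio_trace(samples, rate)
}
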