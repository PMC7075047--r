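# Minimal PCM RIFF/WAVE reader and writer (16- or 32-bit integer, mono or
# multi-channel). Samples are exchanged as doubles in [-1, 1] relative to
# digital full scale.

#' Write a PCM WAV file
#'
#' @param samples numeric vector (mono) or matrix with one column per
#'   channel, values in [-1, 1] relative to digital full scale.
#' @param path output path.
#' @param fs sampling rate, Hz.
#' @param bits 16 or 32 (integer PCM).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, fs, bits = 16L) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (!bits %in% c(16L, 32L)) stopf("bits must be 16 or 32")
  if (max(abs(samples)) > 1 + 1e-12)
    stopf("samples exceed digital full scale (max |x| = %.3g)", max(abs(samples)))
  nch <- ncol(samples); n <- nrow(samples)
  scale <- 2 ^ (bits - 1) - 1
  ints <- as.integer(round(t(samples) * scale))   # interleave channels
  bytes_per <- bits / 8L
  data_size <- n * nch * bytes_per
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")          # PCM
  writeBin(nch, con, size = 2L, endian = "little")
  writeBin(as.integer(fs), con, size = 4L, endian = "little")
  writeBin(as.integer(fs * nch * bytes_per), con, size = 4L, endian = "little")
  writeBin(as.integer(nch * bytes_per), con, size = 2L, endian = "little")
  writeBin(as.integer(bits), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  writeBin(ints, con, size = bytes_per, endian = "little")
  invisible(path)
}

#' Read a PCM WAV file
#'
#' @param path path to a 16- or 32-bit integer PCM WAV file.
#' @return a list with `samples` (matrix, one column per channel, doubles in
#'   [-1, 1]), `fs` and `bits`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  if (readChar(con, 4L) != "RIFF") stopf("%s is not a RIFF file", path)
  readBin(con, integer(), size = 4L, endian = "little")
  if (readChar(con, 4L) != "WAVE") stopf("%s is not a WAVE file", path)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, integer(), size = 4L, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, raw(), n = sz)
    } else if (id == "data") {
      data_raw <- readBin(con, raw(), n = sz)
    } else {
      readBin(con, raw(), n = sz + sz %% 2L)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stopf("malformed WAV file: %s", path)
  u16 <- function(i) sum(as.integer(fmt[i:(i + 1L)]) * c(1L, 256L))
  u32 <- function(i) sum(as.numeric(fmt[i:(i + 3L)]) * 256 ^ (0:3))
  nch <- u16(3L); fs <- u32(5L); bits <- u16(15L)
  if (!bits %in% c(16L, 32L)) stopf("unsupported bit depth: %d", bits)
  ints <- readBin(data_raw, integer(), n = length(data_raw) / (bits / 8L),
                  size = bits / 8L, signed = TRUE, endian = "little")
  scale <- 2 ^ (bits - 1) - 1
  samples <- matrix(ints / scale, ncol = nch, byrow = TRUE)
  list(samples = samples, fs = fs, bits = as.integer(bits))
}
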