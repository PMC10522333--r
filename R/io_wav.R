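#' Read and write multichannel PCM WAV files
#'
#' Minimal RIFF/WAVE codec for 16-bit PCM with any channel count (the
#' recordings here are 64- and 4-channel at 250 kHz, which mainstream R
#' audio packages do not handle). Samples are scaled to [-1, 1] on read;
#' on write they are clipped to [-1, 1] and quantized to 16 bits.
#'
#' @param samples Samples x channels numeric matrix in [-1, 1].
#' @param fs Sample rate (Hz).
#' @param path File path.
#' @return `read_wav_multi`: list with `samples`, `fs`.
#' @export
write_wav_multi <- function(samples, fs, path) {
  samples <- as.matrix(samples)
  nch <- ncol(samples); n <- nrow(samples)
  pcm <- as.integer(round(pmin(pmax(t(samples), -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- n * nch * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(nch, con, size = 2, endian = "little")
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * nch * 2L), con, size = 4, endian = "little")
  writeBin(as.integer(nch * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")          # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav_multi
#' @export
read_wav_multi <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  if (hdr != "RIFF") stop("not a RIFF file")
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fs <- NULL; nch <- NULL; bits <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found")
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1) stop("only PCM supported")
      nch <- fmt[2]
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (bits != 16) stop("only 16-bit PCM supported")
      if (sz > 16) invisible(readBin(con, raw(), n = sz - 16))
    } else if (id == "data") {
      pcm <- readBin(con, integer(), n = sz / 2, size = 2,
                     endian = "little", signed = TRUE)
      samples <- t(matrix(pcm / 32767, nrow = nch))
      return(list(samples = samples, fs = fs))
    } else {
      invisible(readBin(con, raw(), n = sz))
    }
  }
}
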