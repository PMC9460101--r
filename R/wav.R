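# Minimal RIFF/WAV PCM 16-bit mono reader and writer (no audio package is
# assumed). Samples are exchanged as doubles in [-1, 1].

#' Write a mono PCM 16-bit WAV file
#'
#' @param samples Numeric vector in `[-1, 1]` (values are clipped).
#' @param sample_rate Sample rate in Hz.
#' @param path Output file path.
#' @export
write_wav <- function(samples, sample_rate, path) {
  pcm <- as.integer(round(pmin(pmax(samples, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_len <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(data_len, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono PCM 16-bit WAV file
#'
#' @param path File path.
#' @return List with `samples` (doubles in `[-1, 1]`) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  sample_rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) stop("no data chunk found in ", path)
    len <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) stop("only PCM mono is supported")
      sample_rate <- readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 4, endian = "little")
      bits <- readBin(con, "integer", 2, 2, endian = "little")[2]
      if (bits != 16L) stop("only 16-bit PCM is supported")
    } else if (id == "data") {
      pcm <- readBin(con, "integer", len / 2, 2, endian = "little", signed = TRUE)
      return(list(samples = pcm / 32767, sample_rate = sample_rate))
    } else {
      readBin(con, "raw", len)
    }
  }
}
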