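#' Write a waveform as a 32-bit float WAV file
#'
#' Minimal RIFF/WAVE writer (IEEE float, format code 3, mono or multichannel
#' by column). Round-trips losslessly at float32 precision via [read_wav()].
#'
#' @param waveform Numeric vector (mono) or matrix (samples x channels).
#' @param path Output path.
#' @param sample_rate Sampling rate, Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, path, sample_rate) {
  x <- if (is.matrix(waveform)) waveform else matrix(waveform, ncol = 1)
  n_ch <- ncol(x)
  n <- nrow(x)
  data_bytes <- n * n_ch * 4L
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s) writeBin(charToRaw(s), con)
  w32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  wchar("RIFF"); w32(36L + data_bytes); wchar("WAVE")
  wchar("fmt "); w32(16L)
  w16(3L) # IEEE float
  w16(n_ch)
  w32(as.integer(sample_rate))
  w32(as.integer(sample_rate) * n_ch * 4L) # byte rate
  w16(n_ch * 4L) # block align
  w16(32L) # bits per sample
  wchar("data"); w32(data_bytes)
  writeBin(as.numeric(t(x)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a 32-bit float WAV file
#'
#' @param path WAV path (IEEE-float format as written by [write_wav()];
#'   16-bit PCM is also accepted and rescaled to [-1, 1]).
#' @return List with `waveform` (vector if mono, else samples x channels
#'   matrix) and `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rchar <- function(k) rawToChar(readBin(con, "raw", k))
  r32 <- function() readBin(con, "integer", 1L, size = 4L, endian = "little")
  r16 <- function() readBin(con, "integer", 1L, size = 2L, endian = "little")
  if (rchar(4) != "RIFF") abort("not a RIFF file")
  r32()
  if (rchar(4) != "WAVE") abort("not a WAVE file")
  fmt <- NULL
  repeat {
    id <- rchar(4)
    if (!nzchar(id)) abort("malformed WAV: no data chunk")
    size <- r32()
    if (id == "fmt ") {
      fmt <- list(code = r16(), n_ch = r16(), rate = r32())
      r32(); r16()
      fmt$bits <- r16()
      if (size > 16) readBin(con, "raw", size - 16L)
    } else if (id == "data") {
      if (is.null(fmt)) abort("malformed WAV: data before fmt")
      n_samp <- size / (fmt$bits / 8)
      x <- if (fmt$code == 3L) {
        readBin(con, "numeric", n_samp, size = 4L, endian = "little")
      } else if (fmt$code == 1L && fmt$bits == 16L) {
        readBin(con, "integer", n_samp, size = 2L, signed = TRUE,
                endian = "little") / 32768
      } else {
        abort("unsupported WAV encoding (expect float32 or PCM16)")
      }
      wav <- if (fmt$n_ch > 1) t(matrix(x, nrow = fmt$n_ch)) else x
      return(list(waveform = wav, sample_rate = fmt$rate))
    } else {
      readBin(con, "raw", size + size %% 2)
    }
  }
}
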