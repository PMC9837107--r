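## WAV audio input/output (RIFF, PCM 16-bit or IEEE float32) and a
## length-exact resampler for bringing audio to the EEG rate.

#' Write a waveform as WAV
#'
#' @param waveform numeric vector (or channels in columns), nominal
#'   amplitude range -1..1 for PCM
#' @param fs sampling rate (Hz)
#' @param path output path
#' @param format `"pcm16"` (default) or `"float32"`
#' @return the path, invisibly
#' @export
write_wav <- function(waveform, fs, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  x <- as.matrix(waveform)
  n_ch <- ncol(x); n <- nrow(x)
  bits <- if (format == "pcm16") 16L else 32L
  bytes_per <- bits %/% 8L
  block <- n_ch * bytes_per
  data_bytes <- n * block
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  wr(36 + data_bytes, 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  wr(16, 4)
  wr(if (format == "pcm16") 1L else 3L, 2)   # audio format tag
  wr(n_ch, 2)
  wr(fs, 4)
  wr(fs * block, 4)
  wr(block, 2)
  wr(bits, 2)
  writeChar("data", con, eos = NULL)
  wr(data_bytes, 4)
  inter <- as.numeric(t(x))                   # interleave channels
  if (format == "pcm16") {
    writeBin(as.integer(round(pmin(pmax(inter, -1), 1) * 32767)),
             con, size = 2, endian = "little")
  } else {
    writeBin(inter, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file
#'
#' Supports PCM 16-bit and IEEE float32. Stereo (or more channels) is
#' averaged to mono with a message.
#'
#' @param path WAV path
#' @return list with `waveform` (mono numeric vector) and `fs`
#' @export
read_audio <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF/WAV file")
  readBin(con, "integer", 1, 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAV file")
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        tag = sum(as.integer(raw[1:2]) * c(1, 256)),
        n_ch = sum(as.integer(raw[3:4]) * c(1, 256)),
        fs = sum(as.integer(raw[5:8]) * 256^(0:3)),
        bits = sum(as.integer(raw[15:16]) * c(1, 256)))
    } else if (id == "data") {
      data <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz)
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("WAV file missing fmt or data chunk")
  if (fmt$tag == 1 && fmt$bits == 16) {
    x <- readBin(data, "integer", length(data) %/% 2, 2,
                 signed = TRUE, endian = "little") / 32767
  } else if (fmt$tag == 3 && fmt$bits == 32) {
    x <- readBin(data, "numeric", length(data) %/% 4, 4, endian = "little")
  } else stop("unsupported WAV encoding (tag ", fmt$tag, ", ", fmt$bits, " bit)")
  if (fmt$n_ch > 1) {
    message("averaging ", fmt$n_ch, " channels to mono")
    x <- rowMeans(matrix(x, ncol = fmt$n_ch, byrow = TRUE))
  }
  list(waveform = x, fs = fmt$fs)
}

#' Resample a series to a new rate
#'
#' Anti-alias low-pass (when downsampling) followed by linear
#' interpolation on the new sample grid; output length is exactly
#' `round(N * to_fs / from_fs)`.
#'
#' @param x numeric vector
#' @param from_fs,to_fs old and new sampling rates (Hz)
#' @return resampled numeric vector
#' @export
resample_series <- function(x, from_fs, to_fs) {
  if (from_fs == to_fs) return(x)
  if (to_fs < from_fs) x <- lowpass(x, from_fs, 0.4 * to_fs)
  n_out <- round(length(x) * to_fs / from_fs)
  t_old <- (seq_along(x) - 1) / from_fs
  t_new <- (seq_len(n_out) - 1) / to_fs
  stats::approx(t_old, x, xout = pmin(t_new, max(t_old)), rule = 2)$y
}
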