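## EEG file input/output: BrainVision (.vhdr/.vmrk/.eeg, multiplexed
## IEEE float32 little-endian) and EDF (16-bit, 1 s data records).

#' Write an EEG recording as a BrainVision triplet
#'
#' @param rec an `eeg_recording`
#' @param basename path without extension; writes `.vhdr`, `.vmrk`, `.eeg`
#' @return the `.vhdr` path, invisibly
#' @export
write_brainvision <- function(rec, basename) {
  vhdr <- paste0(basename, ".vhdr")
  vmrk <- paste0(basename, ".vmrk")
  eegf <- paste0(basename, ".eeg")
  nm <- basename(basename)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", nm, ".eeg"),
    paste0("MarkerFile=", nm, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    paste0("SamplingInterval=", format(1e6 / rec$fs, scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_len(nrow(rec$data)), rec$channels))
  writeLines(hdr, vhdr, useBytes = TRUE)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "[Common Infos]",
               paste0("DataFile=", nm, ".eeg"),
               "[Marker Infos]",
               "Mk1=New Segment,,1,1,0,0"), vmrk)
  con <- file(eegf, "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  invisible(vhdr)
}

.bv_field <- function(lines, key) {
  hit <- grep(paste0("^", key, "="), lines, value = TRUE)
  if (!length(hit)) stop("BrainVision header missing ", key)
  sub(paste0("^", key, "="), "", hit[1])
}

#' Read a BrainVision recording
#'
#' @param vhdr_path path to the `.vhdr` header
#' @return an `eeg_recording`
#' @export
read_brainvision <- function(vhdr_path) {
  lines <- readLines(vhdr_path, warn = FALSE)
  dir <- dirname(vhdr_path)
  datafile <- file.path(dir, .bv_field(lines, "DataFile"))
  markerfile <- file.path(dir, .bv_field(lines, "MarkerFile"))
  if (!file.exists(markerfile))
    stop("BrainVision marker file not found: ", markerfile)
  if (!file.exists(datafile))
    stop("BrainVision data file not found: ", datafile)
  if (.bv_field(lines, "BinaryFormat") != "IEEE_FLOAT_32")
    stop("only the IEEE_FLOAT_32 BrainVision dialect is supported")
  if (.bv_field(lines, "DataOrientation") != "MULTIPLEXED")
    stop("only MULTIPLEXED BrainVision data are supported")
  n_ch <- as.integer(.bv_field(lines, "NumberOfChannels"))
  fs <- 1e6 / as.numeric(.bv_field(lines, "SamplingInterval"))
  ch_lines <- grep("^Ch[0-9]+=", lines, value = TRUE)
  channels <- vapply(strsplit(sub("^Ch[0-9]+=", "", ch_lines), ","),
                     `[`, "", 1L)
  if (length(channels) != n_ch)
    stop("channel info lines do not match NumberOfChannels")
  sz <- file.size(datafile)
  x <- readBin(datafile, "numeric", sz %/% 4, size = 4, endian = "little")
  data <- matrix(x, nrow = n_ch)
  rownames(data) <- channels
  structure(list(data = data, fs = fs, channels = channels, run = NA_integer_),
            class = "eeg_recording")
}

.pad16 <- function(s, n) formatC(substr(s, 1, n), width = n, flag = "-")

#' Write an EEG recording as EDF
#'
#' 16-bit EDF with 1 s data records; the signal is padded with zeros to a
#' whole number of seconds and quantised to the per-channel physical range,
#' so the round trip is exact only to 16-bit precision.
#'
#' @param rec an `eeg_recording` with integer `fs`
#' @param path output `.edf` path
#' @return the path, invisibly
#' @export
write_edf <- function(rec, path) {
  X <- rec$data
  fs <- as.integer(rec$fs)
  ns <- nrow(X)
  n_rec <- ceiling(ncol(X) / fs)
  if (ncol(X) < n_rec * fs)
    X <- cbind(X, matrix(0, ns, n_rec * fs - ncol(X)))
  pmin_ <- apply(X, 1, min); pmax_ <- apply(X, 1, max)
  flat <- pmax_ <= pmin_
  pmax_[flat] <- pmin_[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  wc <- function(s, n) writeChar(.pad16(s, n), con, nchars = n, eos = NULL)
  wc("0", 8); wc("X X X X", 80); wc("Startdate X X X X", 80)
  wc("01.01.00", 8); wc("00.00.00", 8)
  wc(as.character(256 * (ns + 1)), 8)
  wc("", 44)
  wc(as.character(n_rec), 8)
  wc("1", 8)
  wc(as.character(ns), 4)
  for (ch in rec$channels) wc(ch, 16)
  for (i in seq_len(ns)) wc("", 80)             # transducer
  for (i in seq_len(ns)) wc("uV", 8)
  for (i in seq_len(ns)) wc(format(pmin_[i], digits = 7), 8)
  for (i in seq_len(ns)) wc(format(pmax_[i], digits = 7), 8)
  for (i in seq_len(ns)) wc("-32768", 8)
  for (i in seq_len(ns)) wc("32767", 8)
  for (i in seq_len(ns)) wc("", 80)             # prefiltering
  for (i in seq_len(ns)) wc(as.character(fs), 8)
  for (i in seq_len(ns)) wc("", 32)
  scale <- (pmax_ - pmin_) / 65535
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      d <- round((X[i, cols] - pmin_[i]) / scale[i]) - 32768
      writeBin(as.integer(pmin(pmax(d, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path `.edf` path
#' @return an `eeg_recording`
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                  # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  channels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  X <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", spr[i], 2, signed = TRUE, endian = "little")
      X[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        pmin_[i] + (d - dmin_[i]) * (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
    }
  }
  rownames(X) <- channels
  structure(list(data = X, fs = spr[1] / rec_dur, channels = channels,
                 run = NA_integer_),
            class = "eeg_recording")
}

#' Read an EEG recording, dispatching on extension
#'
#' `.vhdr` goes to [read_brainvision()], `.edf` to [read_edf()].
#'
#' @param path file path
#' @param montage optional `sensor_array`; errors when the recording lacks
#'   any montage channel
#' @return an `eeg_recording`
#' @export
read_eeg <- function(path, montage = NULL) {
  ext <- tolower(tools::file_ext(path))
  rec <- switch(ext,
                vhdr = read_brainvision(path),
                edf = read_edf(path),
                stop("unsupported EEG format: .", ext))
  if (!is.null(montage)) {
    missing_ch <- setdiff(montage$name, rec$channels)
    if (length(missing_ch))
      stop("recording lacks montage channels: ",
           paste(missing_ch, collapse = ", "))
    rec$data <- rec$data[match(montage$name, rec$channels), , drop = FALSE]
    rec$channels <- montage$name
  }
  rec
}
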