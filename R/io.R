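# Recording I/O: the package's own binary container (raw doubles + JSON
# sidecar), a minimal EDF reader/writer and a BrainVision triplet reader,
# so real recordings with event markers can feed the same pipeline as the
# synthetic data.

#' Write / read a recording in the internal container format
#'
#' `<path>.bin` holds the samples as little-endian doubles in channel-major
#' order; `<path>.json` carries channel labels, sampling rate and markers.
#'
#' @param recording an [eeg_recording()]
#' @param path base path (no extension)
#' @return `path` invisibly (writer); an [eeg_recording()] (reader)
#' @export
write_eeg <- function(recording, path) {
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(as.numeric(t(recording$data)), con, size = 8, endian = "little")
  close(con)
  meta <- list(channel_labels = recording$channel_labels,
               fs = recording$fs,
               n_samples = ncol(recording$data),
               markers = recording$markers)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_eeg
#' @export
read_eeg <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  nch <- length(meta$channel_labels)
  con <- file(paste0(path, ".bin"), "rb")
  x <- readBin(con, "double", n = nch * meta$n_samples, size = 8,
               endian = "little")
  close(con)
  markers <- if (is.data.frame(meta$markers) && nrow(meta$markers) > 0)
    data.frame(sample = as.integer(meta$markers$sample),
               label = as.character(meta$markers$label),
               stringsAsFactors = FALSE)
  else data.frame(sample = integer(), label = character())
  eeg_recording(t(matrix(x, meta$n_samples, nch)),
                meta$channel_labels, meta$fs, markers)
}

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

# Most precise "g" representation of a number that fits an 8-char EDF field.
edf_num8 <- function(x) {
  for (d in 7:1) {
    s <- formatC(x, digits = d, format = "g")
    if (nchar(s) <= 8) return(s)
  }
  substr(s, 1, 8)
}

#' Export a recording to EDF
#'
#' Minimal European Data Format writer: one data record per second,
#' 16-bit samples linearly scaled to each channel's physical range. Event
#' markers are not representable in plain EDF and are dropped; use
#' [write_eeg()] to preserve them.
#'
#' @param recording an [eeg_recording()]; `fs` must be a positive integer
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_edf <- function(recording, path) {
  data <- recording$data
  nch <- nrow(data)
  fs <- round(recording$fs)
  n_rec <- floor(ncol(data) / fs)
  if (n_rec < 1) stop_invalid("recording shorter than one 1 s data record")
  data <- data[, seq_len(n_rec * fs), drop = FALSE]
  pmin_ <- apply(data, 1, min); pmax_ <- apply(data, 1, max)
  span <- pmax_ - pmin_
  pmin_[span == 0] <- pmin_[span == 0] - 1
  pmax_[span == 0] <- pmax_[span == 0] + 1
  # snap physical ranges to their 8-char header representation so the
  # reader reconstructs with the same scale
  pmin_ <- vapply(vapply(pmin_, edf_num8, character(1)), as.numeric,
                  numeric(1))
  pmax_ <- vapply(vapply(pmax_, edf_num8, character(1)), as.numeric,
                  numeric(1))
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(pad_field(x, w), con, nchars = w,
                                 eos = NULL)
  wr("0", 8); wr("simulated subject", 80); wr("simulated recording", 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256 * (nch + 1), 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(nch, 4)
  for (lab in recording$channel_labels) wr(lab, 16)
  for (i in seq_len(nch)) wr("EEG", 80)
  for (i in seq_len(nch)) wr("uV", 8)
  for (i in seq_len(nch)) wr(edf_num8(pmin_[i]), 8)
  for (i in seq_len(nch)) wr(edf_num8(pmax_[i]), 8)
  for (i in seq_len(nch)) wr(dmin, 8)
  for (i in seq_len(nch)) wr(dmax, 8)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr(fs, 8)
  for (i in seq_len(nch)) wr("", 32)
  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(nch)) {
      dig <- round((data[i, idx] - pmin_[i]) * scale[i]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Minimal reader for continuous EDF files with equal per-channel sampling
#' rates; samples are rescaled to physical units.
#'
#' @param path EDF file path
#' @return an [eeg_recording()] (no markers)
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                         # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), character(1))
  for (i in seq_len(nch)) rd(80)
  for (i in seq_len(nch)) rd(8)
  pmin_ <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(nch)) rd(80)
  ns <- vapply(seq_len(nch), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(nch)) rd(32)
  if (length(unique(ns)) != 1)
    stop_invalid("EDF files with mixed sampling rates are not supported")
  fs <- ns[1] / rec_dur
  data <- matrix(0, nch, n_rec * ns[1])
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nch)) {
      dig <- readBin(con, "integer", n = ns[i], size = 2, signed = TRUE,
                     endian = "little")
      data[i, ((r - 1) * ns[i] + 1):(r * ns[i])] <-
        (dig - dmin[i]) * scale[i] + pmin_[i]
    }
  }
  eeg_recording(data, labels, fs)
}

#' Read a BrainVision recording
#'
#' Minimal reader for the BrainVision triplet (`.vhdr` header, binary
#' `.eeg` data, `.vmrk` markers): multiplexed IEEE float-32 or int-16
#' binary formats, marker positions and descriptions from the marker file.
#'
#' @param vhdr_path path to the `.vhdr` header file
#' @return an [eeg_recording()]
#' @export
read_brainvision <- function(vhdr_path) {
  hdr <- readLines(vhdr_path, warn = FALSE)
  get_val <- function(key) {
    ln <- grep(paste0("^", key, "="), hdr, value = TRUE)
    if (length(ln) == 0) return(NA_character_)
    sub(paste0("^", key, "="), "", ln[1])
  }
  dir <- dirname(vhdr_path)
  data_file <- file.path(dir, get_val("DataFile"))
  marker_file <- get_val("MarkerFile")
  nch <- as.integer(get_val("NumberOfChannels"))
  fs <- 1e6 / as.numeric(get_val("SamplingInterval"))
  fmt <- get_val("BinaryFormat")
  ch_lines <- grep("^Ch[0-9]+=", hdr, value = TRUE)
  parts <- strsplit(sub("^Ch[0-9]+=", "", ch_lines), ",")
  labels <- vapply(parts, `[`, character(1), 1)
  res <- vapply(parts, function(p)
    if (length(p) >= 3 && nzchar(p[3])) as.numeric(p[3]) else 1, numeric(1))
  sz <- file.info(data_file)$size
  if (identical(fmt, "INT_16")) {
    n <- sz / 2
    raw_v <- readBin(data_file, "integer", n = n, size = 2, signed = TRUE,
                     endian = "little")
    raw_v <- raw_v * rep(res, n / nch)
  } else {
    n <- sz / 4
    raw_v <- readBin(data_file, "double", n = n, size = 4,
                     endian = "little")
  }
  data <- matrix(raw_v, nch, n / nch)      # multiplexed: channels fastest
  markers <- data.frame(sample = integer(), label = character())
  if (!is.na(marker_file) && file.exists(file.path(dir, marker_file))) {
    mk <- readLines(file.path(dir, marker_file), warn = FALSE)
    mk <- grep("^Mk[0-9]+=", mk, value = TRUE)
    mp <- strsplit(sub("^Mk[0-9]+=", "", mk), ",")
    markers <- data.frame(
      sample = vapply(mp, function(p) as.integer(p[3]), integer(1)),
      label = vapply(mp, function(p)
        if (nzchar(p[2])) p[2] else p[1], character(1)),
      stringsAsFactors = FALSE)
  }
  eeg_recording(data, labels, fs, markers)
}
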