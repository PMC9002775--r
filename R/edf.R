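# European Data Format (EDF) I/O.
#
# EDF stores an ASCII header (256 bytes global + 256 per signal) followed by
# data records of 16-bit little-endian integers, one block per signal per
# record. Physical values map linearly between the per-signal physical and
# digital ranges, so a write/read round trip is exact up to one quantization
# step of (phys_max - phys_min) / (dig_max - dig_min).

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = -width, flag = " ")
}

#' Write a multichannel recording to an EDF file
#'
#' One data record per second; all channels share the sampling rate. The
#' physical range is set symmetric around zero and padded slightly so
#' every sample is representable.
#'
#' @param signal Channels x samples numeric matrix.
#' @param path Output file path.
#' @param fs Sampling rate (Hz); `fs` samples per channel per record.
#' @param channel_names Channel labels (default rownames or `ch<i>`).
#' @param patient_id,recording_id Free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signal, path, fs = 500, channel_names = NULL,
                      patient_id = "X", recording_id = "synthetic") {
  signal <- as.matrix(signal)
  nc <- nrow(signal)
  if (is.null(channel_names)) channel_names <- rownames(signal)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nc))
  stopifnot(length(channel_names) == nc, fs > 0)
  spr <- as.integer(fs)                       # samples per record (1 s)
  n_rec <- ncol(signal) %/% spr
  stopifnot(n_rec >= 1)
  used <- signal[, seq_len(n_rec * spr), drop = FALSE]

  amax <- max(abs(used), 1e-6)
  phys_min <- -amax * 1.001
  phys_max <- amax * 1.001
  dig_min <- -32768L; dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field(patient_id, 80), pad_field(recording_id, 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (nc + 1), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field(1, 8), pad_field(nc, 4))
  sig_hdr <- paste0(
    paste(vapply(channel_names, pad_field, "", width = 16), collapse = ""),
    paste(rep(pad_field("", 80), nc), collapse = ""),
    paste(rep(pad_field("uV", 8), nc), collapse = ""),
    paste(rep(pad_field(sprintf("%.6g", phys_min), 8), nc), collapse = ""),
    paste(rep(pad_field(sprintf("%.6g", phys_max), 8), nc), collapse = ""),
    paste(rep(pad_field(dig_min, 8), nc), collapse = ""),
    paste(rep(pad_field(dig_max, 8), nc), collapse = ""),
    paste(rep(pad_field("", 80), nc), collapse = ""),
    paste(rep(pad_field(spr, 8), nc), collapse = ""),
    paste(rep(pad_field("", 32), nc), collapse = ""))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL)

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (rec in seq_len(n_rec)) {
    cols <- ((rec - 1) * spr + 1):(rec * spr)
    block <- t(used[, cols, drop = FALSE])    # per-signal contiguous
    dig <- as.integer(round((block - phys_min) * scale + dig_min))
    dig <- pmin(pmax(dig, dig_min), dig_max)
    writeBin(as.vector(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_header_field <- function(raw, offset, width) {
  trimws(rawToChar(raw[(offset + 1):(offset + width)]))
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return List with `signal` (channels x samples matrix, physical units,
#'   channel names as rownames), `channel_names`, `fs` (per channel),
#'   `n_records`, `record_duration`, `patient_id`, `recording_id`.
#' @export
read_edf <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", sz)
  gv <- function(off, w) read_header_field(raw, off, w)
  patient_id <- gv(8, 80); recording_id <- gv(88, 80)
  n_rec <- as.integer(gv(236, 8))
  rec_dur <- as.numeric(gv(244, 8))
  nc <- as.integer(gv(252, 4))

  off <- 256
  fld <- function(width) {
    out <- vapply(seq_len(nc), function(i)
      read_header_field(raw, off + (i - 1) * width, width), "")
    off <<- off + nc * width
    out
  }
  labels <- fld(16); fld(80); fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)

  data_off <- 256 * (nc + 1)
  total_int <- sum(spr) * n_rec
  ints <- readBin(raw[(data_off + 1):(data_off + 2 * total_int)], "integer",
                  n = total_int, size = 2, signed = TRUE, endian = "little")
  signal <- matrix(0, nc, max(spr) * n_rec)
  pos <- 0
  for (rec in seq_len(n_rec)) for (ch in seq_len(nc)) {
    v <- ints[(pos + 1):(pos + spr[ch])]
    pos <- pos + spr[ch]
    phys <- phys_min[ch] +
      (v - dig_min[ch]) * (phys_max[ch] - phys_min[ch]) /
        (dig_max[ch] - dig_min[ch])
    signal[ch, ((rec - 1) * spr[ch] + 1):(rec * spr[ch])] <- phys
  }
  rownames(signal) <- labels
  list(signal = signal, channel_names = labels, fs = spr / rec_dur,
       n_records = n_rec, record_duration = rec_dur,
       patient_id = patient_id, recording_id = recording_id)
}

#' Export segments as an EDF recording plus a labels table
#'
#' Segments are concatenated in order into one continuous EDF recording
#' (one data record per segment) and the per-second labels written as a
#' CSV with columns `t_start` and `label`.
#'
#' @param segments List of [eeg_segment()] with common channels and rate.
#' @param path EDF output path.
#' @param labels_path Optional CSV path (default `path` with `.csv`).
#' @return Invisible list with both paths.
#' @export
export_edf <- function(segments, path, labels_path = NULL) {
  stopifnot(length(segments) > 0)
  if (is.null(labels_path)) labels_path <- sub("\\.edf$", "_labels.csv", path)
  sig <- do.call(cbind, lapply(segments, function(s) s$data))
  write_edf(sig, path, fs = segments[[1]]$fs,
            channel_names = segments[[1]]$channel_names)
  labels <- data.frame(
    t_start = seq_along(segments) - 1,
    label = vapply(segments, function(s) s$label, integer(1)))
  write.csv(labels, labels_path, row.names = FALSE)
  invisible(list(edf = path, labels = labels_path))
}

#' Import an EDF recording and labels CSV as segments
#'
#' @param path EDF file; `labels_path` CSV with a `label` column, one row
#'   per second.
#' @param drop Channels to drop before segmenting (default none).
#' @return List of [eeg_segment()].
#' @export
import_edf <- function(path, labels_path, drop = character(0)) {
  rec <- read_edf(path)
  labels <- read.csv(labels_path)$label
  sig <- drop_channels(rec$signal, drop)
  segment_recording(sig, fs = rec$fs[1], labels = labels,
                    subject_id = rec$patient_id)
}
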