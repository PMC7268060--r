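## Minimal EDF (European Data Format) writer/reader.
##
## EDF stores 16-bit samples with per-signal physical/digital scaling in
## fixed-width ASCII headers. One data record per second is used here.
## Trial events are stored in a sidecar TSV (<path>.events.tsv) rather than
## EDF+ annotation signals; subject/session metadata go into the patient and
## recording identification fields.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

num_field <- function(x, width) pad_field(format(x, trim = TRUE, scientific = FALSE, digits = 8), width)

#' Write a continuous recording to an EDF file
#'
#' Samples are quantized to 16 bits over a symmetric physical range per
#' channel. The recording is zero-padded to a whole number of 1 s data
#' records. Events (when present) are written to `<path>.events.tsv`.
#'
#' @param rec an `erd_recording`.
#' @param path output file path (conventionally `.edf`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "erd_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stopf("EDF writer requires an integer sampling rate")
  x <- rec$samples
  ns <- nrow(x)
  spr <- as.integer(round(fs))                 # samples per record per signal
  n_rec <- as.integer(ceiling(ncol(x) / spr))
  if (ncol(x) < n_rec * spr)
    x <- cbind(x, matrix(0, ns, n_rec * spr - ncol(x)))

  pmax_ <- apply(abs(x), 1L, max)
  pmax_[pmax_ == 0] <- 1
  pmax_ <- signif(pmax_ * 1.0001, 6)           # avoid clipping the extremes
  dig_max <- 32767; dig_min <- -32768

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(rec$subject_id %||% "X", 80),
    pad_field(sprintf("session %d lesion %s",
                      rec$session_index %||% -1L,
                      rec$lesion_side %||% "unknown"), 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    num_field(256 + 256 * ns, 8),
    pad_field("", 44),
    num_field(n_rec, 8), num_field(1, 8), num_field(ns, 4))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  fields <- list(
    pad_field(rec$channel_labels, 16),
    pad_field(rep("", ns), 80),
    pad_field(rep("uV", ns), 8),
    num_field(-pmax_, 8),
    num_field(pmax_, 8),
    num_field(rep(dig_min, ns), 8),
    num_field(rep(dig_max, ns), 8),
    pad_field(rep("", ns), 80),
    num_field(rep(spr, ns), 8),
    pad_field(rep("", ns), 32))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL, useBytes = TRUE)

  scale <- (dig_max - dig_min) / (2 * pmax_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns)) {
      dig <- round((x[s, idx] + pmax_[s]) * scale[s]) + dig_min
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2L, endian = "little")
    }
  }

  if (!is.null(rec$events) && nrow(rec$events))
    utils::write.table(rec$events, paste0(path, ".events.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an EDF file written by [write_edf()] (or any plain EDF)
#'
#' @param path EDF file path; a sidecar `<path>.events.tsv` is read when
#'   present.
#' @return an `erd_recording`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd_num <- function(w) as.numeric(rd_str(w))
  rd_str(8)                                   # version
  patient <- rd_str(80)
  recording_id <- rd_str(80)
  rd_str(8); rd_str(8); rd_num(8); rd_str(44)
  n_rec <- rd_num(8); rec_dur <- rd_num(8); ns <- as.integer(rd_num(4))
  rd_vec <- function(w, fun = rd_str) vapply(seq_len(ns), function(i) fun(w), if (identical(fun, rd_str)) "" else 0)
  labels <- rd_vec(16)
  rd_vec(80); rd_vec(8)
  pmin_ <- rd_vec(8, rd_num); pmax_ <- rd_vec(8, rd_num)
  dmin  <- rd_vec(8, rd_num); dmax  <- rd_vec(8, rd_num)
  rd_vec(80)
  spr <- as.integer(rd_vec(8, rd_num))
  rd_vec(32)

  if (length(unique(spr)) != 1L)
    stopf("mixed per-signal sampling rates are not supported")
  fs <- spr[1] / rec_dur
  x <- matrix(0, ns, n_rec * spr[1])
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2L,
                     signed = TRUE, endian = "little")
      x[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        (dig - dmin[s]) * gain[s] + pmin_[s]
    }
  }
  rownames(x) <- labels

  meta <- parse_recording_id(recording_id)
  ev_path <- paste0(path, ".events.tsv")
  events <- if (file.exists(ev_path))
    utils::read.table(ev_path, header = TRUE, sep = "\t") else NULL
  continuous_recording(x, fs, channel_labels = labels, events = events,
                       subject_id = patient,
                       session_index = meta$session_index,
                       lesion_side = meta$lesion_side)
}

parse_recording_id <- function(txt) {
  m <- regmatches(txt, regexec("session ([-0-9]+) lesion (\\w+)", txt))[[1]]
  if (length(m) == 3L)
    list(session_index = as.integer(m[2]), lesion_side = m[3])
  else list(session_index = NA_integer_, lesion_side = NA_character_)
}
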