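## Minimal BrainVision (.vhdr/.vmrk/.eeg) writer/reader.
##
## Supports multiplexed binary data in IEEE_FLOAT_32 or INT_16 (with
## per-channel resolution). Trial events are encoded as Stimulus markers at
## the preparation-phase onset ("S  2"); ITI/phase durations are written as
## a sidecar TSV like the EDF path, and reconstructed from it when present.

#' Write a recording as a BrainVision triplet
#'
#' @param rec an `erd_recording`.
#' @param base base path without extension; writes `<base>.vhdr`,
#'   `<base>.vmrk`, `<base>.eeg` (and `<base>.events.tsv` when events are
#'   present).
#' @param binary_format `"IEEE_FLOAT_32"` or `"INT_16"`.
#' @return the `.vhdr` path, invisibly.
#' @export
write_brainvision <- function(rec, base, binary_format = "IEEE_FLOAT_32") {
  stopifnot(inherits(rec, "erd_recording"))
  binary_format <- match.arg(binary_format, c("IEEE_FLOAT_32", "INT_16"))
  vhdr <- paste0(base, ".vhdr"); vmrk <- paste0(base, ".vmrk")
  eeg <- paste0(base, ".eeg")
  x <- rec$samples
  ns <- nrow(x)
  res <- if (binary_format == "INT_16") {
    r <- apply(abs(x), 1L, max) / 32000
    r[r == 0] <- 1e-3
    signif(r, 6)
  } else rep(1, ns)

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    sprintf("DataFile=%s", basename(eeg)),
    sprintf("MarkerFile=%s", basename(vmrk)),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", ns),
    sprintf("SamplingInterval=%s", format(1e6 / rec$fs, scientific = FALSE)),
    "",
    "[Binary Infos]",
    sprintf("BinaryFormat=%s", binary_format),
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%s,µV", seq_len(ns), rec$channel_labels,
            format(res, scientific = FALSE, trim = TRUE)))
  writeLines(hdr, vhdr)

  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "",
          "[Common Infos]",
          sprintf("DataFile=%s", basename(eeg)),
          "",
          "[Marker Infos]",
          "Mk1=New Segment,,1,1,0")
  if (!is.null(rec$events) && nrow(rec$events)) {
    mk <- c(mk, sprintf("Mk%d=Stimulus,S  2,%d,1,0",
                        seq_len(nrow(rec$events)) + 1L,
                        rec$events$onset + 1L))   # vmrk positions are 1-based
    utils::write.table(rec$events, paste0(base, ".events.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  writeLines(mk, vmrk)

  con <- file(eeg, "wb")
  on.exit(close(con))
  if (binary_format == "IEEE_FLOAT_32") {
    writeBin(as.numeric(as.vector(x)), con, size = 4L, endian = "little")
  } else {
    dig <- round(sweep(x, 1L, res, "/"))
    writeBin(as.integer(pmin(pmax(as.vector(dig), -32768), 32767)), con,
             size = 2L, endian = "little")
  }
  invisible(vhdr)
}

parse_vhdr_ini <- function(lines) {
  section <- ""
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    if (grepl("^\\s*\\[", ln)) {
      section <- gsub("\\[|\\]", "", trimws(ln))
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && nzchar(section)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    }
  }
  out
}

#' Read a BrainVision recording
#'
#' @param path path to the `.vhdr` header (or base path without extension).
#' @return an `erd_recording`. Events come from the sidecar
#'   `<base>.events.tsv` when present, otherwise from `Stimulus` markers in
#'   the `.vmrk` file (with default 2 s preparation / 5 s movement phases
#'   and ITIs inferred from marker spacing).
#' @export
read_brainvision <- function(path) {
  if (!grepl("\\.vhdr$", path)) path <- paste0(path, ".vhdr")
  if (!file.exists(path)) stopf("header file not found: %s", path)
  ini <- parse_vhdr_ini(readLines(path, warn = FALSE, encoding = "UTF-8"))
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  chi <- ini[["Channel Infos"]]
  if (!identical(ci$DataFormat, "BINARY") ||
      !identical(ci$DataOrientation, "MULTIPLEXED"))
    stopf("only BINARY MULTIPLEXED BrainVision data are supported")
  ns <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)
  ch <- t(vapply(seq_len(ns), function(i) {
    parts <- strsplit(chi[[sprintf("Ch%d", i)]], ",")[[1]]
    c(parts[1], if (length(parts) >= 3 && nzchar(parts[3])) parts[3] else "1")
  }, character(2)))
  labels <- ch[, 1]
  res <- as.numeric(ch[, 2])

  eeg_path <- file.path(dirname(path), ci$DataFile)
  fmt <- bi$BinaryFormat %||% "IEEE_FLOAT_32"
  sz <- file.info(eeg_path)$size
  if (fmt == "IEEE_FLOAT_32") {
    n <- sz / 4
    raw_data <- readBin(eeg_path, "numeric", n = n, size = 4L, endian = "little")
  } else if (fmt == "INT_16") {
    n <- sz / 2
    raw_data <- readBin(eeg_path, "integer", n = n, size = 2L,
                        signed = TRUE, endian = "little")
  } else stopf("unsupported BinaryFormat: %s", fmt)
  x <- matrix(raw_data, nrow = ns)
  x <- x * res                                  # recycles per channel (rows)
  rownames(x) <- labels

  base <- sub("\\.vhdr$", "", path)
  ev_path <- paste0(base, ".events.tsv")
  events <- if (file.exists(ev_path)) {
    utils::read.table(ev_path, header = TRUE, sep = "\t")
  } else {
    vmrk_path <- file.path(dirname(path), ci$MarkerFile %||% "")
    events_from_vmrk(vmrk_path, fs)
  }
  continuous_recording(x, fs, channel_labels = labels, events = events)
}

events_from_vmrk <- function(vmrk_path, fs, prep_s = 2, move_s = 5) {
  if (!nzchar(vmrk_path) || !file.exists(vmrk_path)) return(NULL)
  lines <- grep("^Mk[0-9]+=Stimulus", readLines(vmrk_path, warn = FALSE),
                value = TRUE)
  if (!length(lines)) return(NULL)
  pos <- vapply(lines, function(ln)
    as.integer(strsplit(sub("^Mk[0-9]+=", "", ln), ",")[[1]][3]), 0L,
    USE.NAMES = FALSE)
  onset <- sort(pos) - 1L                       # back to 0-based
  prev_end <- c(0L, onset[-length(onset)] + round((prep_s + move_s) * fs))
  data.frame(trial = seq_along(onset), onset = onset,
             iti_s = (onset - prev_end) / fs,
             prep_s = prep_s, move_s = move_s)
}
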