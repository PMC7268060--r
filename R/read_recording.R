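#' Read a recording from a standard EEG file format
#'
#' Dispatches to the EDF or BrainVision reader, infers channel kinds from
#' labels (overridable via `channel_map`), normalizes metadata and checks
#' that required channels are present.
#'
#' @param path file path (`.edf` or `.vhdr`/base path).
#' @param format `"edf"` or `"brainvision"`; guessed from the extension when
#'   missing.
#' @param channel_map optional named character vector or YAML file path
#'   mapping channel labels to kinds (`EEG`, `EOG`, `EMG`).
#' @param required_channels channels that must be present; an error names
#'   any that are missing. Defaults to the six motor channels used for ERD
#'   extraction.
#' @return an `erd_recording`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "brainvision"),
                           channel_map = NULL,
                           required_channels = c("C3", "Cp3", "P3",
                                                 "C4", "Cp4", "P4")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else if (grepl("\\.vhdr$", path, ignore.case = TRUE)) "brainvision"
              else stopf("cannot guess format of '%s'; pass format=", path)
  }
  rec <- switch(format,
                edf = read_edf(path),
                brainvision = read_brainvision(path))
  if (!is.null(channel_map)) {
    if (is.character(channel_map) && length(channel_map) == 1L &&
        file.exists(channel_map))
      channel_map <- unlist(yaml::read_yaml(channel_map))
    known <- intersect(names(channel_map), rec$channel_labels)
    rec$channel_kinds[known] <- channel_map[known]
  }
  missing <- setdiff(required_channels, rec$channel_labels)
  if (length(missing))
    stopf("recording lacks required channels: %s",
          paste(missing, collapse = ", "))
  rec
}
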