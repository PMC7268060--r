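#' Continuous multichannel recording
#'
#' Container for one training session of continuous EEG/EOG/EMG data plus
#' trial event markers. Sample indices in `events` are 0-based; all epochs
#' derived from them are half-open intervals `[start, end)` in samples.
#'
#' @param samples channels x time numeric matrix, microvolts, with channel
#'   labels as row names.
#' @param fs sampling rate in Hz.
#' @param channel_labels ordered channel names (defaults to row names).
#' @param channel_kinds named vector `EEG`/`EOG`/`EMG` per channel; inferred
#'   from labels when `NULL`.
#' @param events data frame with one row per trial: `onset` (0-based sample
#'   of the preparation-phase start), `iti_s`, `prep_s`, `move_s`.
#' @param subject_id,session_index,lesion_side session metadata
#'   (`session_index` is 0-based chronological).
#' @return object of class `erd_recording`.
#' @export
continuous_recording <- function(samples, fs, channel_labels = rownames(samples),
                                 channel_kinds = NULL, events = NULL,
                                 subject_id = NA_character_,
                                 session_index = NA_integer_,
                                 lesion_side = NA_character_) {
  if (fs <= 0) stopf("fs must be positive")
  if (is.null(channel_labels)) stopf("channel labels are required")
  if (anyDuplicated(channel_labels)) stopf("channel labels must be unique")
  rownames(samples) <- channel_labels
  channel_kinds <- channel_kinds %||% infer_channel_kinds(channel_labels)
  n <- ncol(samples)
  if (!is.null(events) && nrow(events)) {
    if (is.unsorted(events$onset, strictly = TRUE))
      stopf("event onsets must be strictly increasing")
    rest_start <- events$onset - 4 * fs
    trial_end  <- events$onset + (events$prep_s + events$move_s) * fs
    if (any(rest_start < 0) || any(trial_end > n))
      stopf("event phase boundaries fall outside the recording")
  }
  structure(list(samples = samples, fs = fs,
                 channel_labels = channel_labels,
                 channel_kinds = channel_kinds,
                 events = events,
                 subject_id = subject_id,
                 session_index = as.integer(session_index),
                 lesion_side = lesion_side),
            class = "erd_recording")
}

#' @export
print.erd_recording <- function(x, ...) {
  cat(sprintf("<erd_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              if (is.null(x$events)) 0L else nrow(x$events)))
  invisible(x)
}

#' Assemble a simulated session into a continuous recording
#'
#' Concatenates the trials of an [simulate_session()] session in order
#' (ITI, preparation, movement per trial) and builds the matching event
#' table, so that [epoch_trials()] recovers the trials sample-exactly.
#'
#' @param session an `erd_session`.
#' @return an `erd_recording`.
#' @export
session_to_recording <- function(session) {
  stopifnot(inherits(session, "erd_session"))
  fs <- session$fs
  mats <- lapply(session$trials, function(tr) cbind(tr$iti, tr$prep, tr$move))
  samples <- do.call(cbind, mats)
  onset <- integer(length(session$trials))
  pos <- 0L
  ev <- vector("list", length(session$trials))
  for (i in seq_along(session$trials)) {
    tr <- session$trials[[i]]
    onset_i <- pos + ncol(tr$iti)              # 0-based prep onset
    ev[[i]] <- data.frame(trial = i, onset = onset_i,
                          iti_s = ncol(tr$iti) / fs,
                          prep_s = ncol(tr$prep) / fs,
                          move_s = ncol(tr$move) / fs)
    pos <- pos + ncol(tr$iti) + ncol(tr$prep) + ncol(tr$move)
  }
  continuous_recording(samples, fs,
                       channel_labels = session$channel_labels,
                       channel_kinds = session$channel_kinds,
                       events = do.call(rbind, ev),
                       subject_id = session$subject_id,
                       session_index = session$session_index,
                       lesion_side = session$lesion_side)
}

#' Cut a continuous recording into phase-labeled trials
#'
#' For each event the rest segment is the last 4 s of the inter-trial
#' interval (`[onset - 4 s, onset)`), followed by the preparation and
#' movement segments. Trials whose ITI is shorter than 4 s are dropped (the
#' reference-window duration is fixed, never shrunk) and logged.
#'
#' @param rec an `erd_recording` with events.
#' @return an `erd_epochs` object: list with `trials` (each with `rest`,
#'   `prep`, `move` channels x samples matrices and `trial` index), channel
#'   metadata, and a `dropped` data frame of discarded trials with reasons.
#' @export
epoch_trials <- function(rec) {
  stopifnot(inherits(rec, "erd_recording"))
  fs <- rec$fs
  ev <- rec$events
  if (is.null(ev) || nrow(ev) == 0L) {
    warnf("no events present; returning empty epochs")
    ev <- data.frame(trial = integer(), onset = integer(),
                     iti_s = numeric(), prep_s = numeric(), move_s = numeric())
  }
  n_rest <- round(4 * fs)
  trials <- list()
  dropped <- list()
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    if (e$iti_s < 4) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(trial = e$trial, reason = sprintf("ITI %.2f s < 4 s", e$iti_s))
      next
    }
    onset1 <- e$onset + 1L                      # first preparation sample, 1-based
    n_prep <- round(e$prep_s * fs)
    n_move <- round(e$move_s * fs)
    rest <- rec$samples[, (onset1 - n_rest):(onset1 - 1L), drop = FALSE]
    prep <- rec$samples[, onset1:(onset1 + n_prep - 1L), drop = FALSE]
    move <- rec$samples[, (onset1 + n_prep):(onset1 + n_prep + n_move - 1L),
                        drop = FALSE]
    trials[[length(trials) + 1L]] <-
      list(trial = e$trial, rest = rest, prep = prep, move = move)
  }
  structure(list(trials = trials, fs = fs,
                 channel_labels = rec$channel_labels,
                 channel_kinds = rec$channel_kinds,
                 subject_id = rec$subject_id,
                 session_index = rec$session_index,
                 lesion_side = rec$lesion_side,
                 dropped = if (length(dropped)) do.call(rbind, dropped)
                           else data.frame(trial = integer(), reason = character())),
            class = "erd_epochs")
}

#' @export
print.erd_epochs <- function(x, ...) {
  cat(sprintf("<erd_epochs> %d trials (%d dropped), %d channels @ %g Hz\n",
              length(x$trials), nrow(x$dropped), length(x$channel_labels), x$fs))
  invisible(x)
}

#' Convert a simulated session directly to epochs
#'
#' Shortcut equivalent to `epoch_trials(session_to_recording(session))`,
#' but without materializing the continuous matrix: the rest segment is the
#' last 4 s of each trial's ITI.
#'
#' @param session an `erd_session`.
#' @return an `erd_epochs` object.
#' @export
session_to_epochs <- function(session) {
  stopifnot(inherits(session, "erd_session"))
  n_rest <- round(4 * session$fs)
  trials <- lapply(seq_along(session$trials), function(i) {
    tr <- session$trials[[i]]
    n_iti <- ncol(tr$iti)
    list(trial = i,
         rest = tr$iti[, (n_iti - n_rest + 1L):n_iti, drop = FALSE],
         prep = tr$prep, move = tr$move)
  })
  structure(list(trials = trials, fs = session$fs,
                 channel_labels = session$channel_labels,
                 channel_kinds = session$channel_kinds,
                 subject_id = session$subject_id,
                 session_index = session$session_index,
                 lesion_side = session$lesion_side,
                 dropped = data.frame(trial = integer(), reason = character())),
            class = "erd_epochs")
}
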