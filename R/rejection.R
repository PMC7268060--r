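#' Configuration of the automated artifact-rejection cascade
#'
#' Thresholds and windows of the four-step rejection procedure: ICA-based
#' ocular artifact removal, a high-frequency (cranial EMG) z-score detector,
#' a broadband offset detector, and waveform-length detection of
#' compensatory muscle contractions in the EMG, followed by session/subject
#' exclusion rules.
#'
#' The per-sample statistic of the z-score detectors is the per-channel
#' z-value (session mean/SD per channel) summed across EEG channels and
#' normalized by `sqrt(n_channels)`, the convention of the established
#' artifact-rejection toolboxes: it has unit variance for independent
#' channels yet grows as `sqrt(k) * z` when an artifact hits `k` channels
#' coherently. A trial is flagged when the statistic strictly exceeds the
#' threshold somewhere inside the trial.
#'
#' @param hf_band high-frequency detection band in Hz.
#' @param hf_z_threshold threshold (SD units) of the high-frequency detector.
#' @param offset_z_threshold threshold (SD units) of the broadband offset
#'   detector.
#' @param emg_wl_sd_threshold EMG waveform-length threshold in session SDs
#'   above the session mean.
#' @param emg_wl_window_s EMG waveform-length window (s), non-overlapping.
#' @param min_trials_per_session,min_fraction a session is excluded when
#'   fewer than `max(min_trials_per_session, ceiling(min_fraction * total))`
#'   trials survive.
#' @param max_removed_sessions_fraction a subject is excluded when at least
#'   `ceiling(fraction * n_sessions)` sessions were removed.
#' @param eog_component_corr_threshold absolute Pearson correlation with an
#'   EOG channel above which an independent component is removed.
#' @param ica_seed seed of the ICA initialization (determinism).
#' @return object of class `rejection_config`.
#' @export
rejection_config <- function(hf_band = c(110, 140),
                             hf_z_threshold = 4,
                             offset_z_threshold = 20,
                             emg_wl_sd_threshold = 3,
                             emg_wl_window_s = 0.25,
                             min_trials_per_session = 16L,
                             min_fraction = 0.10,
                             max_removed_sessions_fraction = 0.5,
                             eog_component_corr_threshold = 0.7,
                             ica_seed = 1L) {
  cfg <- list(hf_band = hf_band, hf_z_threshold = hf_z_threshold,
              offset_z_threshold = offset_z_threshold,
              emg_wl_sd_threshold = emg_wl_sd_threshold,
              emg_wl_window_s = emg_wl_window_s,
              min_trials_per_session = as.integer(min_trials_per_session),
              min_fraction = min_fraction,
              max_removed_sessions_fraction = max_removed_sessions_fraction,
              eog_component_corr_threshold = eog_component_corr_threshold,
              ica_seed = as.integer(ica_seed))
  stopifnot(cfg$hf_z_threshold > 0, cfg$offset_z_threshold > 0,
            cfg$emg_wl_sd_threshold > 0,
            cfg$min_fraction > 0, cfg$min_fraction < 1,
            cfg$eog_component_corr_threshold > 0,
            cfg$eog_component_corr_threshold < 1)
  structure(cfg, class = "rejection_config")
}

#' Remove ocular artifacts by ICA
#'
#' Decomposes the EEG channels into independent components and zeroes every
#' component whose absolute Pearson correlation with any EOG channel exceeds
#' the configured threshold; the EEG is then reconstructed from the
#' remaining components. EOG channels themselves are left untouched.
#'
#' @param rec an `erd_recording` with at least one EOG channel.
#' @param config a [rejection_config()].
#' @return list with `recording` (cleaned), `removed_components` (indices),
#'   and `correlations` (components x EOG channels matrix).
#' @export
remove_eog <- function(rec, config = rejection_config()) {
  stopifnot(inherits(rec, "erd_recording"))
  eeg_idx <- which(rec$channel_kinds == "EEG")
  eog_idx <- which(rec$channel_kinds == "EOG")
  if (!length(eog_idx)) stopf("no EOG channel present")
  X <- rec$samples[eeg_idx, , drop = FALSE]
  ica <- fast_ica(X, seed = config$ica_seed)
  eog <- rec$samples[eog_idx, , drop = FALSE]
  cors <- matrix(0, nrow(ica$S), nrow(eog),
                 dimnames = list(NULL, rownames(eog)))
  for (k in seq_len(nrow(ica$S)))
    for (j in seq_len(nrow(eog)))
      cors[k, j] <- safe_cor(ica$S[k, ], eog[j, ])
  removed <- which(apply(abs(cors), 1L, max) > config$eog_component_corr_threshold)
  if (length(removed)) {
    S2 <- ica$S
    S2[removed, ] <- 0
    rec$samples[eeg_idx, ] <- ica$A %*% S2 + ica$center
  }
  list(recording = rec, removed_components = removed, correlations = cors)
}

## Combined z statistic per sample: sum of per-channel z over sqrt(N).
## stats: list(mean, sd) per channel computed over the whole session.
session_channel_stats <- function(epochs, channels, transform = identity) {
  acc_n <- 0
  acc_s <- setNames(numeric(length(channels)), channels)
  acc_s2 <- setNames(numeric(length(channels)), channels)
  for (tr in epochs$trials) {
    x <- cbind(tr$rest, tr$prep, tr$move)[channels, , drop = FALSE]
    x <- transform(x)
    acc_n <- acc_n + ncol(x)
    acc_s <- acc_s + rowSums(x)
    acc_s2 <- acc_s2 + rowSums(x^2)
  }
  mu <- acc_s / acc_n
  sd_ <- sqrt(pmax(acc_s2 / acc_n - mu^2, 0))
  sd_[sd_ == 0] <- 1
  list(mean = mu, sd = sd_)
}

zscore_detector <- function(epochs, threshold, filter_fun = NULL) {
  channels <- epochs$channel_labels[epochs$channel_kinds == "EEG"]
  transform <- if (is.null(filter_fun)) identity else function(x)
    t(apply(x, 1L, filter_fun))
  st <- session_channel_stats(epochs, channels, transform)
  nch <- length(channels)
  stat <- vapply(epochs$trials, function(tr) {
    x <- cbind(tr$rest, tr$prep, tr$move)[channels, , drop = FALSE]
    x <- transform(x)
    z <- (x - st$mean) / st$sd
    max(abs(colSums(z))) / sqrt(nch)   # abs: offset jumps may go either way
  }, 0)
  list(flag = stat > threshold, stat = stat)
}

#' Detect high-frequency (cranial EMG) artifacts
#'
#' Band-pass filters the EEG channels in the configured high-frequency band,
#' z-scores each channel against the session's per-channel statistics,
#' combines z across channels (`sum/sqrt(N)`), and flags every trial whose
#' combined statistic strictly exceeds the threshold at any sample.
#'
#' @param epochs an `erd_epochs` object (one session).
#' @param config a [rejection_config()].
#' @return list with `flag` (logical per trial) and `stat` (per-trial
#'   maximum of the combined z statistic).
#' @export
detect_hf_emg <- function(epochs, config = rejection_config()) {
  stopifnot(inherits(epochs, "erd_epochs"))
  if (epochs$fs < 2 * config$hf_band[2])
    stopf("sampling rate %g Hz too low for band up to %g Hz",
          epochs$fs, config$hf_band[2])
  fs <- epochs$fs
  band <- config$hf_band
  zscore_detector(epochs, config$hf_z_threshold,
                  filter_fun = function(v) fft_bandpass(v, fs, band[1], band[2]))
}

#' Detect offset artifacts on the broadband EEG
#'
#' Same z-score procedure as [detect_hf_emg()] but on the unfiltered signal
#' with the (much higher) offset threshold.
#'
#' @inheritParams detect_hf_emg
#' @return list with `flag` and `stat` as in [detect_hf_emg()].
#' @export
detect_offset <- function(epochs, config = rejection_config()) {
  stopifnot(inherits(epochs, "erd_epochs"))
  zscore_detector(epochs, config$offset_z_threshold)
}

#' Waveform length of a signal in non-overlapping windows
#'
#' The waveform length of a window is the sum of absolute successive-sample
#' differences, a standard surface-EMG activity measure.
#'
#' @param x numeric vector.
#' @param window_s window length in seconds.
#' @param fs sampling rate in Hz.
#' @return numeric vector, one waveform-length value per complete window.
#' @export
waveform_length <- function(x, window_s, fs) {
  if (!length(x)) stopf("empty segment")
  nw <- max(2L, round(window_s * fs))
  if (length(x) < nw) stopf("segment shorter than the waveform-length window")
  n_win <- length(x) %/% nw
  vapply(seq_len(n_win), function(k) {
    sum(abs(diff(x[((k - 1L) * nw + 1L):(k * nw)])))
  }, 0)
}

#' Detect compensatory muscle contractions in the EMG
#'
#' Computes the waveform length of every EMG channel in sliding
#' (non-overlapping) windows per trial phase; a contraction is a window
#' whose waveform length exceeds the channel's session mean by more than the
#' configured number of session SDs. A trial is flagged when a paretic-side
#' contraction overlaps the rest period, or a healthy-side contraction
#' overlaps the movement phase (the two compensation patterns that
#' invalidate a training trial).
#'
#' @param epochs an `erd_epochs` object with EMG channels labeled by side
#'   (`_L`/`_R` suffix) and a known `lesion_side` (the paretic arm is
#'   contralateral to the lesion).
#' @param config a [rejection_config()].
#' @return list with `flag` (per trial), `flag_rest_paretic`,
#'   `flag_move_healthy`, and `detail` (per-trial/channel/phase contraction
#'   counts).
#' @export
detect_emg_movement <- function(epochs, config = rejection_config()) {
  stopifnot(inherits(epochs, "erd_epochs"))
  emg <- epochs$channel_labels[epochs$channel_kinds == "EMG"]
  if (!length(emg)) stopf("no EMG channels present")
  sides <- emg_channel_side(emg)
  if (anyNA(sides)) stopf("EMG channels lack side labels (_L/_R suffix)")
  if (!epochs$lesion_side %in% c("left", "right"))
    stopf("lesion side required to identify the paretic arm")
  paretic_side <- if (epochs$lesion_side == "left") "right" else "left"
  fs <- epochs$fs; ws <- config$emg_wl_window_s

  ## session waveform-length distribution per channel (all trials, all phases)
  wl_all <- lapply(setNames(emg, emg), function(ch) {
    unlist(lapply(epochs$trials, function(tr) {
      c(waveform_length(tr$rest[ch, ], ws, fs),
        waveform_length(tr$prep[ch, ], ws, fs),
        waveform_length(tr$move[ch, ], ws, fs))
    }))
  })
  thr <- vapply(wl_all, function(v) mean(v) + config$emg_wl_sd_threshold * stats::sd(v), 0)

  n_tr <- length(epochs$trials)
  f_rest <- logical(n_tr); f_move <- logical(n_tr)
  detail <- list()
  for (i in seq_len(n_tr)) {
    tr <- epochs$trials[[i]]
    for (ch in emg) {
      rest_hits <- sum(waveform_length(tr$rest[ch, ], ws, fs) > thr[ch])
      move_hits <- sum(waveform_length(tr$move[ch, ], ws, fs) > thr[ch])
      if (sides[ch] == paretic_side && rest_hits > 0) f_rest[i] <- TRUE
      if (sides[ch] != paretic_side && move_hits > 0) f_move[i] <- TRUE
      if (rest_hits + move_hits > 0)
        detail[[length(detail) + 1L]] <- data.frame(
          trial = i, channel = ch, side = sides[[ch]],
          rest_hits = rest_hits, move_hits = move_hits)
    }
  }
  list(flag = f_rest | f_move,
       flag_rest_paretic = f_rest, flag_move_healthy = f_move,
       detail = if (length(detail)) do.call(rbind, detail) else NULL)
}

#' Run all trial-level detectors on one session
#'
#' @param epochs an `erd_epochs` object.
#' @param config a [rejection_config()].
#' @return data frame, one row per trial, with logical columns `hf_emg`,
#'   `offset`, `emg_rest_paretic`, `emg_move_healthy` and `removed`.
#' @export
flag_trials <- function(epochs, config = rejection_config()) {
  hf <- detect_hf_emg(epochs, config)
  off <- detect_offset(epochs, config)
  emg <- detect_emg_movement(epochs, config)
  out <- data.frame(trial = vapply(epochs$trials, `[[`, 0L, "trial"),
                    hf_emg = hf$flag, offset = off$flag,
                    emg_rest_paretic = emg$flag_rest_paretic,
                    emg_move_healthy = emg$flag_move_healthy)
  out$removed <- out$hf_emg | out$offset | out$emg_rest_paretic |
    out$emg_move_healthy
  out
}

#' Apply session and subject exclusion rules
#'
#' A session is excluded when fewer than
#' `max(min_trials_per_session, ceiling(min_fraction * n_trials))` trials
#' survive trial-level rejection; a subject is excluded when at least
#' `ceiling(max_removed_sessions_fraction * n_sessions)` sessions were
#' removed.
#'
#' @param session_reports list of per-session trial flag tables as returned
#'   by [flag_trials()], each carrying attributes or list fields `subject`
#'   and `session`; alternatively a single data frame with `subject`,
#'   `session` and the flag columns.
#' @param config a [rejection_config()].
#' @return object of class `rejection_report`: list with `trials` (tidy
#'   per-trial flags), `sessions` (per-session counts and exclusion flags)
#'   and `subjects` (per-subject exclusion flags).
#' @export
apply_exclusions <- function(session_reports, config = rejection_config()) {
  trials <- if (is.data.frame(session_reports)) session_reports
            else do.call(rbind, session_reports)
  stopifnot(all(c("subject", "session", "removed") %in% names(trials)))
  agg <- stats::aggregate(cbind(n_in = removed, n_removed = removed) ~ subject + session,
                          data = transform(trials, removed = as.logical(removed)),
                          FUN = function(v) c(length(v), sum(v)))
  sessions <- data.frame(subject = agg$subject, session = agg$session,
                         n_in = agg$n_in[, 1], n_removed = agg$n_removed[, 2])
  sessions$n_out <- sessions$n_in - sessions$n_removed
  sessions$min_required <- pmax(config$min_trials_per_session,
                                ceiling(config$min_fraction * sessions$n_in))
  sessions$excluded <- sessions$n_out < sessions$min_required

  subj_split <- split(sessions, sessions$subject)
  subjects <- do.call(rbind, lapply(subj_split, function(df) {
    n_sess <- nrow(df); n_removed <- sum(df$excluded)
    data.frame(subject = df$subject[1], n_sessions = n_sess,
               n_removed_sessions = n_removed,
               excluded = n_removed >= ceiling(
                 config$max_removed_sessions_fraction * n_sess))
  }))
  rownames(subjects) <- NULL
  structure(list(trials = trials, sessions = sessions, subjects = subjects),
            class = "rejection_report")
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("<rejection_report> %d trials (%d removed), %d sessions (%d excluded), %d subjects (%d excluded)\n",
              nrow(x$trials), sum(x$trials$removed),
              nrow(x$sessions), sum(x$sessions$excluded),
              nrow(x$subjects), sum(x$subjects$excluded)))
  invisible(x)
}

#' Serialize a rejection report
#'
#' Writes the per-trial flags as TSV and the session/subject summaries as a
#' JSON file.
#'
#' @param report a `rejection_report`.
#' @param dir output directory.
#' @return paths of the written files, invisibly.
#' @export
write_rejection_report <- function(report, dir) {
  stopifnot(inherits(report, "rejection_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(dir, "rejection_trials.tsv")
  utils::write.table(report$trials, tsv, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  js <- file.path(dir, "rejection_summary.json")
  jsonlite::write_json(list(sessions = report$sessions,
                            subjects = report$subjects),
                       js, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(tsv, js))
}
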