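## Artifact injection with ground-truth logging.
##
## Four artifact classes mirror the contamination seen in BMI training data:
##   eog    - blink-like low-frequency deflections on EOG + frontal EEG
##   hf     - 110-140 Hz cranial-EMG bursts on a few scalp channels
##   offset - DC jumps across all EEG channels (electrode/cap shifts)
##   emg    - compensatory muscle bursts: paretic arm during rest, or the
##            healthy arm during the movement-attempt phase

CRANIAL_CHANNELS <- c("Fp1", "Fp2", "T7", "T8", "F3", "F4")

#' Inject artifacts into a simulated session
#'
#' For each trial and artifact type, an independent Bernoulli draw at the
#' configured rate decides whether one artifact of that type is injected.
#' Every injection is recorded in the session's artifact log (ground truth
#' for detector validation).
#'
#' @param session an `erd_session` from [simulate_session()].
#' @param artifact_rates named per-trial probabilities for
#'   `eog`, `hf`, `offset`, `emg`; defaults to the session spec's rates when
#'   supplied via `spec`, otherwise must be given.
#' @param blink_amp blink amplitude on the vertical EOG channel (microvolts).
#' @param hf_snr high-frequency burst amplitude as a multiple of the
#'   channel's in-band (110-140 Hz) background SD.
#' @param offset_snr DC jump amplitude as a multiple of each channel's
#'   broadband SD.
#' @param emg_snr EMG burst amplitude as a multiple of the channel's
#'   baseline SD.
#' @return the session with modified trials and a populated `artifact_log`
#'   data frame (`trial`, `type`, `channel`, `phase`, `onset_sample` 0-based
#'   within the trial, `duration_samples`).
#' @export
inject_artifacts <- function(session, artifact_rates,
                             blink_amp = 150, hf_snr = 10,
                             offset_snr = 25, emg_snr = 10) {
  stopifnot(inherits(session, "erd_session"))
  known <- c("eog", "hf", "offset", "emg")
  if (is.null(names(artifact_rates)) || !all(names(artifact_rates) %in% known))
    stopf("unknown artifact type in rates: %s",
          paste(setdiff(names(artifact_rates), known), collapse = ", "))
  if (any(artifact_rates < 0 | artifact_rates > 1))
    stopf("artifact rates must lie in [0, 1]")
  rates <- artifact_rates[known]
  rates[is.na(rates)] <- 0
  names(rates) <- known
  fs <- session$fs
  paretic <- if (session$lesion_side == "left") "right" else "left"
  healthy <- session$lesion_side
  log <- list()

  for (ti in seq_along(session$trials)) {
    tr <- session$trials[[ti]]
    n_iti <- ncol(tr$iti); n_prep <- ncol(tr$prep); n_move <- ncol(tr$move)
    n_tot <- n_iti + n_prep + n_move
    x <- cbind(tr$iti, tr$prep, tr$move)

    ## artifacts are placed inside the analyzed span of the trial (from the
    ## start of the 4 s reference window onward); earlier ITI samples never
    ## reach the detectors
    lo <- max(1L, n_iti - round(4 * fs) + 1L)
    if (stats::runif(1) < rates[["eog"]]) {
      res <- inject_blink(x, fs, blink_amp, lo)
      x <- res$x
      log[[length(log) + 1L]] <- cbind(trial = ti, res$log)
    }
    if (stats::runif(1) < rates[["hf"]]) {
      res <- inject_hf_burst(x, fs, hf_snr, lo = lo)
      x <- res$x
      log[[length(log) + 1L]] <- cbind(trial = ti, res$log)
    }
    if (stats::runif(1) < rates[["offset"]]) {
      res <- inject_offset(x, offset_snr, lo)
      x <- res$x
      log[[length(log) + 1L]] <- cbind(trial = ti, res$log)
    }
    if (stats::runif(1) < rates[["emg"]]) {
      res <- inject_emg_burst(x, fs, n_iti, n_prep, n_move,
                              paretic, healthy, emg_snr)
      x <- res$x
      log[[length(log) + 1L]] <- cbind(trial = ti, res$log)
    }

    tr$iti  <- x[, seq_len(n_iti), drop = FALSE]
    tr$prep <- x[, n_iti + seq_len(n_prep), drop = FALSE]
    tr$move <- x[, n_iti + n_prep + seq_len(n_move), drop = FALSE]
    session$trials[[ti]] <- tr
  }

  session$artifact_log <- if (length(log)) {
    out <- do.call(rbind, log)
    rownames(out) <- NULL
    out
  } else empty_artifact_log()
  session
}

phase_of_sample <- function(onset, n_iti, n_prep) {
  if (onset <= n_iti) "iti" else if (onset <= n_iti + n_prep) "prep" else "move"
}

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))

inject_blink <- function(x, fs, blink_amp, lo = 1L) {
  n_tot <- ncol(x)
  width <- round(0.4 * fs)
  onset <- sample(lo:max(lo, n_tot - width), 1L)
  idx <- onset:(onset + width - 1L)
  pulse <- blink_amp * exp(-((seq_len(width) - width / 2)^2) / (2 * (width / 6)^2))
  gains <- c(EOGv = 1, EOGh = 0.4, Fp1 = 0.5, Fp2 = 0.5,
             F3 = 0.2, Fz = 0.2, F4 = 0.2)
  for (ch in names(gains)) x[ch, idx] <- x[ch, idx] + gains[[ch]] * pulse
  list(x = x, log = data.frame(type = "eog", channel = names(gains),
                               phase = NA_character_,
                               onset_sample = onset - 1L,
                               duration_samples = width,
                               stringsAsFactors = FALSE))
}

inject_hf_burst <- function(x, fs, hf_snr, band = c(110, 140), lo = 1L) {
  n_tot <- ncol(x)
  width <- round(0.2 * fs)
  onset <- sample(lo:max(lo, n_tot - width), 1L)
  idx <- onset:(onset + width - 1L)
  chans <- sample(CRANIAL_CHANNELS, 3L)
  burst_core <- fft_bandpass(stats::rnorm(width), fs, band[1], band[2]) *
    hann_window(width)
  burst_core <- burst_core / stats::sd(burst_core)   # in-burst SD = 1 after windowing
  for (ch in chans) {
    bg_sd <- stats::sd(fft_bandpass(x[ch, ], fs, band[1], band[2]))
    if (bg_sd == 0) bg_sd <- 1
    x[ch, idx] <- x[ch, idx] + hf_snr * bg_sd * burst_core
  }
  list(x = x, log = data.frame(type = "hf", channel = chans,
                               phase = NA_character_,
                               onset_sample = onset - 1L,
                               duration_samples = width,
                               stringsAsFactors = FALSE))
}

inject_offset <- function(x, offset_snr, lo = 1L) {
  n_tot <- ncol(x)
  onset <- sample(lo:(n_tot - 1L), 1L)
  sign <- sample(c(-1, 1), 1L)
  eeg <- EEG_CHANNELS
  for (ch in eeg) {
    s <- stats::sd(x[ch, ]); if (s == 0) s <- 1
    x[ch, onset:n_tot] <- x[ch, onset:n_tot] + sign * offset_snr * s
  }
  list(x = x, log = data.frame(type = "offset", channel = eeg,
                               phase = NA_character_,
                               onset_sample = onset - 1L,
                               duration_samples = n_tot - onset + 1L,
                               stringsAsFactors = FALSE))
}

inject_emg_burst <- function(x, fs, n_iti, n_prep, n_move,
                             paretic, healthy, emg_snr) {
  variant <- sample(c("emg_rest_paretic", "emg_move_healthy"), 1L)
  width <- round(0.5 * fs)
  rest_start <- n_iti - round(4 * fs) + 1L   # rest window = last 4 s of ITI
  if (variant == "emg_rest_paretic") {
    side <- paretic
    lo <- rest_start; hi <- n_iti - width
  } else {
    side <- healthy
    lo <- n_iti + n_prep + 1L; hi <- n_iti + n_prep + n_move - width
  }
  onset <- if (hi > lo) sample(lo:hi, 1L) else lo
  idx <- onset:(onset + width - 1L)
  suffix <- if (side == "left") "_L$" else "_R$"
  ch <- sample(grep(paste0("^EMG_.*", suffix), rownames(x), value = TRUE), 1L)
  s <- stats::sd(x[ch, ]); if (s == 0) s <- 1
  x[ch, idx] <- x[ch, idx] + emg_snr * s * stats::rnorm(width) * hann_window(width)
  list(x = x, log = data.frame(type = variant, channel = ch,
                               phase = phase_of_sample(onset, n_iti, n_prep),
                               onset_sample = onset - 1L,
                               duration_samples = width,
                               stringsAsFactors = FALSE))
}
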