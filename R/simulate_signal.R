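## Synthetic multichannel trial generation.
##
## Each trial carries a sensorimotor alpha rhythm over the motor channels of
## both hemispheres (C3/Cp3/P3 and C4/Cp4/P4, with decreasing gain away from
## the central electrode) on top of 1/f and white background noise. During
## the movement phase the alpha amplitude is scaled by sqrt(1 + ERD/100) so
## that the oscillatory band-power ratio movement/rest equals 1 + ERD/100.

MOTOR_LEFT  <- c("C3", "Cp3", "P3")
MOTOR_RIGHT <- c("C4", "Cp4", "P4")
MOTOR_GAINS <- c(1, 0.85, 0.7)

#' Simulate one multichannel training trial
#'
#' Generates one trial of the training protocol: an inter-trial interval
#' (rest), a preparation phase and a movement phase across 16 EEG, 2 EOG and
#' 8 EMG channels. The sensorimotor alpha oscillation over each hemisphere's
#' motor channels is attenuated during the movement phase according to the
#' requested event-related desynchronization.
#'
#' @param spec a [cohort_spec()]; supplies sampling rate, timing and
#'   amplitudes.
#' @param target_erd target ERD in percent (`>= -100`); a scalar applies to
#'   both hemispheres, or a named vector `c(left = , right = )`.
#' @param smr_freq sensorimotor rhythm frequency in Hz.
#' @param iti_s inter-trial interval duration in seconds; drawn uniformly
#'   from the spec's range when `NULL`.
#' @param noise logical; `FALSE` switches off all background noise (pure
#'   oscillation), used for analytic oracle tests.
#' @return a list of class `erd_trial` with elements `iti`, `prep`, `move`
#'   (channels x samples matrices, microvolts), `fs`, `channel_labels`,
#'   `channel_kinds`, `iti_s`, and `analytic`: a data frame of the
#'   generator's expected alpha mean-square power (amplitude^2/2) per motor
#'   channel at rest and during movement.
#' @details Trial phases are contiguous: `cbind(iti, prep, move)` is the
#'   continuous recording span of the trial. The ERD reference window is the
#'   last 4 s of `iti`.
#' @export
simulate_trial <- function(spec, target_erd, smr_freq = 10.6,
                           iti_s = NULL, noise = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  erd <- expand_target_erd(target_erd)
  fs <- spec$fs
  tt <- spec$trial_timing
  if (is.null(iti_s)) iti_s <- stats::runif(1, tt$iti_range_s[1], tt$iti_range_s[2])
  n_iti  <- round(iti_s * fs)
  n_prep <- round(tt$prep_s * fs)
  n_move <- round(tt$move_s * fs)
  n_tot  <- n_iti + n_prep + n_move
  amp <- spec$amplitudes
  nch <- length(ALL_CHANNELS)

  x <- matrix(0, nrow = nch, ncol = n_tot,
              dimnames = list(ALL_CHANNELS, NULL))
  if (noise) {
    for (ch in seq_len(nch)) {
      kind <- ALL_KINDS[[ch]]
      x[ch, ] <- switch(kind,
        EEG = pink_noise(n_tot, amp$pink) + stats::rnorm(n_tot, sd = amp$white),
        EOG = stats::rnorm(n_tot, sd = amp$eog),
        EMG = stats::rnorm(n_tot, sd = amp$emg))
    }
  }

  ## alpha rhythm: amplitude envelope constant at rest/preparation, scaled
  ## during movement; phase continuous across the whole trial
  t_all <- (seq_len(n_tot) - 1) / fs
  move_start <- n_iti + n_prep + 1L
  analytic <- list()
  for (hemi in c("left", "right")) {
    chans <- if (hemi == "left") MOTOR_LEFT else MOTOR_RIGHT
    scale_move <- sqrt(1 + erd[[hemi]] / 100)
    phase <- stats::runif(1, 0, 2 * pi)
    carrier <- sin(2 * pi * smr_freq * t_all + phase)
    env <- rep(1, n_tot)
    env[move_start:n_tot] <- scale_move
    for (k in seq_along(chans)) {
      a <- amp$alpha_rest * MOTOR_GAINS[k]
      x[chans[k], ] <- x[chans[k], ] + a * env * carrier
      analytic[[length(analytic) + 1L]] <- data.frame(
        channel = chans[k], hemisphere_side = hemi,
        rest_power = a^2 / 2,
        move_power = (a * scale_move)^2 / 2)
    }
  }

  structure(list(
    iti  = x[, seq_len(n_iti), drop = FALSE],
    prep = x[, n_iti + seq_len(n_prep), drop = FALSE],
    move = x[, n_iti + n_prep + seq_len(n_move), drop = FALSE],
    fs = fs, iti_s = iti_s,
    channel_labels = ALL_CHANNELS,
    channel_kinds = ALL_KINDS,
    smr_freq = smr_freq,
    target_erd = erd,
    analytic = do.call(rbind, analytic)),
    class = "erd_trial")
}

expand_target_erd <- function(target_erd) {
  if (length(target_erd) == 1L && is.null(names(target_erd)))
    target_erd <- c(left = unname(target_erd), right = unname(target_erd))
  if (!all(c("left", "right") %in% names(target_erd)))
    stopf("target_erd must be a scalar or named c(left =, right =)")
  if (any(target_erd < -100))
    stopf("target_erd below -100%% requested: band power cannot be negative")
  as.list(target_erd[c("left", "right")])
}

#' Simulate one training session as a set of trials
#'
#' @param spec a [cohort_spec()].
#' @param target_erd as in [simulate_trial()] (session-mean target).
#' @param n_trials number of trials; defaults to the spec's nominal count.
#' @param smr_freq sensorimotor rhythm frequency in Hz.
#' @param subject_id,session_index,lesion_side session metadata.
#' @param noise passed to [simulate_trial()].
#' @return an object of class `erd_session`: list with `trials` (list of
#'   `erd_trial`), metadata fields, and an empty artifact log.
#' @export
simulate_session <- function(spec, target_erd, n_trials = NULL,
                             smr_freq = 10.6, subject_id = "S01",
                             session_index = 0L, lesion_side = "left",
                             noise = TRUE) {
  n_trials <- n_trials %||% spec$trials_per_session
  trials <- lapply(seq_len(n_trials), function(i)
    simulate_trial(spec, target_erd, smr_freq = smr_freq, noise = noise))
  structure(list(trials = trials, fs = spec$fs,
                 channel_labels = ALL_CHANNELS,
                 channel_kinds = ALL_KINDS,
                 subject_id = subject_id,
                 session_index = as.integer(session_index),
                 lesion_side = lesion_side,
                 artifact_log = empty_artifact_log()),
            class = "erd_session")
}

empty_artifact_log <- function() {
  data.frame(trial = integer(), type = character(), channel = character(),
             phase = character(), onset_sample = integer(),
             duration_samples = integer(), stringsAsFactors = FALSE)
}
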