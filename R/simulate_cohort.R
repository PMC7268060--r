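#' Simulate a training cohort with known ground truth
#'
#' Draws per-subject, per-hemisphere ERD trajectories (random intercepts and
#' slopes around the population values), session-level ERD targets, clinical
#' outcomes from the stage-2 interaction model, and - optionally - the raw
#' multichannel EEG/EMG signals of every session with injected artifacts.
#'
#' Two signal levels are supported. `signal = "erd"` (default) emits the
#' session-level ERD table directly from the trajectory model; this is the
#' scale at which the statistical pipeline operates and is cheap enough for
#' cohorts of tens of subjects and hundreds of sessions. `signal = "raw"`
#' additionally generates every trial's multichannel signals (alpha rhythm
#' modulated by the session's target ERD, 1/f + white background, EMG/EOG
#' channels) and injects artifacts at the spec's rates; intended for small
#' configurations when exercising the full signal chain.
#'
#' @param spec a [cohort_spec()].
#' @param signal `"erd"` or `"raw"`.
#' @return object of class `erd_cohort`: list with
#'   \describe{
#'     \item{spec}{the input spec.}
#'     \item{subjects}{per-subject table: lesion side, SMR frequency, true
#'       ipsi-/contralesional intercepts and slopes, true and noisy
#'       clinical change, baseline and post cFMA scores.}
#'     \item{erd}{session-level ERD table (subject, session, hemisphere,
#'       band, erd_percent) - the generator's session targets.}
#'     \item{outcomes}{`delta_cfma` table (subject, baseline1, baseline2,
#'       post, delta).}
#'     \item{sessions}{(raw mode only) nested list of `erd_session`
#'       objects per subject.}
#'     \item{ground_truth}{trajectories, session targets and the full
#'       artifact log (raw mode).}
#'   }
#' @export
simulate_cohort <- function(spec, signal = c("erd", "raw")) {
  validate_cohort_spec(spec)
  signal <- match.arg(signal)
  with_seed(spec$seed, simulate_cohort_impl(spec, signal))
}

simulate_cohort_impl <- function(spec, signal) {
  n <- spec$n_subjects
  subj_ids <- sprintf("S%02d", seq_len(n))
  lesion <- if (identical(spec$lesion_side_assignment, "alternate"))
    rep(c("left", "right"), length.out = n) else spec$lesion_side_assignment

  draw_re <- function() {
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    b0 <- spec$sd_b0 * z1
    b1 <- spec$sd_b1 * (spec$rho_b * z1 + sqrt(1 - spec$rho_b^2) * z2)
    cbind(I = spec$beta0 + b0, S = spec$beta1 + b1)
  }
  re_ipsi <- draw_re()
  re_contra <- draw_re()

  smr <- stats::rnorm(n, spec$smr_freq_mean, spec$smr_freq_sd)
  smr <- pmin(pmax(smr, 8.5), 11.5)

  n_sessions <- rep(spec$sessions_per_subject, n)
  if (spec$session_jitter_sd > 0)
    n_sessions <- pmax(4L, round(stats::rnorm(n, spec$sessions_per_subject,
                                              spec$session_jitter_sd)))

  ## clinical outcome from the ipsilesional trajectory
  I <- re_ipsi[, "I"]; S <- re_ipsi[, "S"]
  g <- spec$gamma
  delta_true <- g[1] + g[2] * I + g[3] * S + g[4] * I * S
  delta <- delta_true + stats::rnorm(n, sd = spec$sigma_out)
  base_mean <- draw_baseline_cfma(n, delta, spec)
  d_split <- stats::rnorm(n, sd = 1)
  ## both baselines must stay on the 0-54 scale: |d| <= min(b, 54 - b)
  d_split <- pmin(abs(d_split), base_mean, 54 - base_mean) * sign(d_split)
  baseline1 <- base_mean + d_split
  baseline2 <- base_mean - d_split
  post <- base_mean + delta

  subjects <- data.frame(subject = subj_ids, lesion_side = lesion,
                         smr_freq = smr, n_sessions = n_sessions,
                         I_ipsi = I, S_ipsi = S,
                         I_contra = re_contra[, "I"], S_contra = re_contra[, "S"],
                         delta_true = delta_true, delta = delta)
  outcomes <- data.frame(subject = subj_ids,
                         baseline1 = baseline1, baseline2 = baseline2,
                         post = post, delta = post - (baseline1 + baseline2) / 2)

  ## session-level ERD targets (0-based session index)
  erd_rows <- list()
  for (i in seq_len(n)) {
    js <- 0:(n_sessions[i] - 1L)
    for (h in c("ipsilesional", "contralesional")) {
      tr <- if (h == "ipsilesional") re_ipsi[i, ] else re_contra[i, ]
      target <- tr[["I"]] + tr[["S"]] * js +
        stats::rnorm(length(js), sd = spec$sigma_eps)
      target <- pmax(target, -100)
      erd_rows[[length(erd_rows) + 1L]] <-
        data.frame(subject = subj_ids[i], session = js, hemisphere = h,
                   band = "alpha", erd_percent = target)
    }
  }
  erd <- do.call(rbind, erd_rows)

  cohort <- list(spec = spec, subjects = subjects, erd = erd,
                 outcomes = outcomes, sessions = NULL,
                 ground_truth = list(trajectories = subjects,
                                     session_targets = erd,
                                     artifact_log = NULL))
  class(cohort) <- "erd_cohort"
  if (signal == "raw") cohort <- add_raw_signals(cohort)
  cohort
}

draw_baseline_cfma <- function(n, delta, spec) {
  lo <- pmax(0, -delta); hi <- pmin(54, 54 - delta)
  vapply(seq_len(n), function(i) {
    for (k in seq_len(100)) {
      b <- stats::rnorm(1, spec$baseline_cfma_mean, spec$baseline_cfma_sd)
      if (b >= lo[i] && b <= hi[i]) return(b)
    }
    (lo[i] + hi[i]) / 2
  }, 0)
}

add_raw_signals <- function(cohort) {
  spec <- cohort$spec
  subjects <- cohort$subjects
  sessions <- vector("list", nrow(subjects))
  names(sessions) <- subjects$subject
  art_logs <- list()
  for (i in seq_len(nrow(subjects))) {
    sub <- subjects[i, ]
    hemi2side <- if (sub$lesion_side == "left")
      c(ipsilesional = "left", contralesional = "right") else
      c(ipsilesional = "right", contralesional = "left")
    n_trials <- spec$trials_per_session
    if (spec$trial_jitter_sd > 0)
      n_trials <- max(10L, round(stats::rnorm(1, spec$trials_per_session,
                                              spec$trial_jitter_sd)))
    subj_sessions <- vector("list", sub$n_sessions)
    for (j in seq_len(sub$n_sessions)) {
      erd_j <- cohort$erd[cohort$erd$subject == sub$subject &
                          cohort$erd$session == j - 1L, ]
      target <- c(left = NA_real_, right = NA_real_)
      target[hemi2side[["ipsilesional"]]] <-
        erd_j$erd_percent[erd_j$hemisphere == "ipsilesional"]
      target[hemi2side[["contralesional"]]] <-
        erd_j$erd_percent[erd_j$hemisphere == "contralesional"]
      ses <- simulate_session(spec, target, n_trials = n_trials,
                              smr_freq = sub$smr_freq,
                              subject_id = sub$subject,
                              session_index = j - 1L,
                              lesion_side = sub$lesion_side)
      ses <- inject_artifacts(ses, spec$artifact_rates)
      if (nrow(ses$artifact_log))
        art_logs[[length(art_logs) + 1L]] <-
          cbind(subject = sub$subject, session = j - 1L, ses$artifact_log)
      subj_sessions[[j]] <- ses
    }
    sessions[[i]] <- subj_sessions
  }
  cohort$sessions <- sessions
  cohort$ground_truth$artifact_log <-
    if (length(art_logs)) do.call(rbind, art_logs) else empty_artifact_log()
  cohort
}

#' @export
print.erd_cohort <- function(x, ...) {
  cat(sprintf("<erd_cohort> %d subjects, %d ERD samples%s\n",
              nrow(x$subjects), nrow(x$erd),
              if (is.null(x$sessions)) " (trajectory level)" else " (+ raw signals)"))
  invisible(x)
}

#' Write cohort tables and ground truth to a directory
#'
#' Emits the spec as YAML, the ERD table, outcomes and ground-truth
#' trajectories as TSV, and (raw mode) each session as an EDF file.
#'
#' @param cohort an `erd_cohort`.
#' @param dir output directory.
#' @param write_signals write EDF session files when raw signals are present.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_signals = !is.null(cohort$sessions)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_spec(cohort$spec, file.path(dir, "cohort_spec.yaml"))
  tsv <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  tsv(cohort$erd, "erd_sessions.tsv")
  tsv(cohort$outcomes, "outcomes.tsv")
  tsv(cohort$subjects, "ground_truth_subjects.tsv")
  if (!is.null(cohort$ground_truth$artifact_log) &&
      nrow(cohort$ground_truth$artifact_log))
    tsv(cohort$ground_truth$artifact_log, "ground_truth_artifacts.tsv")
  if (write_signals && !is.null(cohort$sessions)) {
    for (sid in names(cohort$sessions))
      for (ses in cohort$sessions[[sid]])
        write_edf(session_to_recording(ses),
                  file.path(dir, sprintf("%s_ses%02d.edf", sid,
                                         ses$session_index)))
  }
  invisible(dir)
}
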