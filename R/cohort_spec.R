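#' Parameterization of a synthetic training cohort
#'
#' Describes a cohort of chronic stroke patients undergoing several weeks of
#' brain-machine-interface training: how many subjects and sessions, the trial
#' timing of each training run, the population ERD trajectory model, the
#' clinical outcome model, artifact contamination rates and the signal
#' amplitudes of the generated EEG/EMG.
#'
#' The trajectory model is a linear mixed-effects model on the session-mean
#' event-related desynchronization (ERD, in percent): subject `i` at 0-based
#' session `j` has mean ERD `I_i + S_i * j` with `(I_i, S_i)` drawn from a
#' bivariate normal around `(beta0, beta1)` with standard deviations
#' `(sd_b0, sd_b1)` and correlation `rho_b`, plus session-level residual noise
#' `sigma_eps`. The clinical change is generated from the interaction model
#' `DeltaCFMA_i = gamma[1] + gamma[2] * I_i + gamma[3] * S_i +
#' gamma[4] * I_i * S_i + N(0, sigma_out)` using the ipsilesional trajectory.
#'
#' Defaults encode the training protocol of the emulated study: 17 +/- 1.8
#' sessions of 165 +/- 19.5 trials, trials made of an inter-trial interval of
#' 4-7 s, a 2 s preparation phase and a 5 s movement phase, sampled at 500 Hz
#' over a 16-channel cap with 2 EOG and 8 bipolar EMG channels.
#'
#' @param n_subjects number of subjects.
#' @param sessions_per_subject nominal sessions per subject.
#' @param session_jitter_sd SD of the per-subject session-count jitter
#'   (Gaussian, rounded; 0 disables jitter).
#' @param trials_per_session nominal trials per session.
#' @param trial_jitter_sd SD of the per-session trial-count jitter.
#' @param fs sampling rate in Hz.
#' @param trial_timing list with `iti_range_s` (length-2, within 4-7 s),
#'   `prep_s` and `move_s`.
#' @param beta0,beta1 population initial ERD (percent) and ERD change per
#'   session (percent/session).
#' @param sd_b0,sd_b1 random-effect SDs of intercept and slope.
#' @param rho_b intercept-slope random-effect correlation, in `[-1, 1]`.
#' @param sigma_eps residual SD of the session-mean ERD (percent).
#' @param gamma length-4 outcome-model coefficients
#'   `(gamma0, gamma1, gamma2, gamma3)`.
#' @param sigma_out outcome residual SD (cFMA points).
#' @param artifact_rates named per-trial injection probabilities for types
#'   `eog`, `hf`, `offset`, `emg`.
#' @param lesion_side_assignment `"alternate"` or a character vector of
#'   `"left"`/`"right"` per subject.
#' @param smr_freq_mean,smr_freq_sd mean/SD of the per-subject sensorimotor
#'   rhythm frequency (Hz); draws are truncated to 8.5-11.5 Hz so the planted
#'   rhythm stays inside the alpha band.
#' @param amplitudes list of signal scales in microvolts: `alpha_rest`
#'   (resting alpha oscillation amplitude on the primary motor channel),
#'   `pink` (1/f background SD), `white` (measurement noise SD), `emg`
#'   (baseline EMG SD), `eog` (baseline EOG SD).
#' @param baseline_cfma_mean,baseline_cfma_sd population mean/SD of the
#'   baseline combined Fugl-Meyer score (0-54 scale).
#' @param seed integer RNG seed; identical seeds give identical cohorts.
#' @return an object of class `cohort_spec` (a validated list).
#' @examples
#' spec <- cohort_spec(n_subjects = 4, sessions_per_subject = 5,
#'                     trials_per_session = 10, session_jitter_sd = 0,
#'                     trial_jitter_sd = 0)
#' spec$beta0
#' @export
cohort_spec <- function(n_subjects = 22,
                        sessions_per_subject = 17,
                        session_jitter_sd = 1.8,
                        trials_per_session = 165,
                        trial_jitter_sd = 19.5,
                        fs = 500,
                        trial_timing = list(iti_range_s = c(4, 7),
                                            prep_s = 2, move_s = 5),
                        beta0 = -30, beta1 = -0.5,
                        sd_b0 = 10, sd_b1 = 0.4, rho_b = 0,
                        sigma_eps = 8,
                        gamma = c(2, 0.05, -4, -0.15),
                        sigma_out = 3,
                        artifact_rates = c(eog = 0.05, hf = 0.02,
                                           offset = 0.01, emg = 0.05),
                        lesion_side_assignment = "alternate",
                        smr_freq_mean = 10.6, smr_freq_sd = 1,
                        amplitudes = list(alpha_rest = 10, pink = 5,
                                          white = 2, emg = 5, eog = 4),
                        baseline_cfma_mean = 12.22,
                        baseline_cfma_sd = 8.82,
                        seed = 1L) {
  spec <- list(n_subjects = as.integer(n_subjects),
               sessions_per_subject = as.integer(sessions_per_subject),
               session_jitter_sd = session_jitter_sd,
               trials_per_session = as.integer(trials_per_session),
               trial_jitter_sd = trial_jitter_sd,
               fs = fs, trial_timing = trial_timing,
               beta0 = beta0, beta1 = beta1,
               sd_b0 = sd_b0, sd_b1 = sd_b1, rho_b = rho_b,
               sigma_eps = sigma_eps,
               gamma = gamma, sigma_out = sigma_out,
               artifact_rates = artifact_rates,
               lesion_side_assignment = lesion_side_assignment,
               smr_freq_mean = smr_freq_mean, smr_freq_sd = smr_freq_sd,
               amplitudes = amplitudes,
               baseline_cfma_mean = baseline_cfma_mean,
               baseline_cfma_sd = baseline_cfma_sd,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

#' Validate a cohort specification
#'
#' Checks the structural invariants: probabilities in `[0, 1]`, nonnegative
#' SDs, a positive-semidefinite random-effects correlation and trial phase
#' durations compatible with the training protocol (inter-trial interval at
#' least 4 s, since its last 4 s are the ERD reference window).
#'
#' @param spec a `cohort_spec`.
#' @return the spec, invisibly unchanged, or an error.
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$n_subjects < 1L) stopf("n_subjects must be >= 1")
  if (spec$sessions_per_subject < 1L) stopf("sessions_per_subject must be >= 1")
  if (spec$trials_per_session < 1L) stopf("trials_per_session must be >= 1")
  if (spec$fs <= 0) stopf("fs must be positive")
  tt <- spec$trial_timing
  if (length(tt$iti_range_s) != 2L || tt$iti_range_s[1] > tt$iti_range_s[2])
    stopf("iti_range_s must be an increasing pair")
  if (tt$iti_range_s[1] < 4)
    stopf("inter-trial interval must be at least 4 s (ERD reference window)")
  if (tt$prep_s <= 0 || tt$move_s <= 0)
    stopf("preparation and movement phases must have positive duration")
  for (nm in c("sd_b0", "sd_b1", "sigma_eps", "sigma_out",
               "session_jitter_sd", "trial_jitter_sd"))
    if (spec[[nm]] < 0) stopf("%s must be >= 0", nm)
  if (abs(spec$rho_b) > 1)
    stopf("random-effects covariance not positive semi-definite: |rho_b| > 1")
  if (length(spec$gamma) != 4L) stopf("gamma must have length 4")
  rates <- spec$artifact_rates
  if (is.null(names(rates)) || !all(names(rates) %in% c("eog", "hf", "offset", "emg")))
    stopf("artifact_rates must be named with types eog, hf, offset, emg")
  if (any(rates < 0 | rates > 1)) stopf("artifact rates must lie in [0, 1]")
  lsa <- spec$lesion_side_assignment
  if (!(identical(lsa, "alternate") ||
        (length(lsa) == spec$n_subjects && all(lsa %in% c("left", "right")))))
    stopf("lesion_side_assignment must be \"alternate\" or left/right per subject")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d subjects, %d sessions x %d trials, fs = %g Hz\n",
              x$n_subjects, x$sessions_per_subject, x$trials_per_session, x$fs))
  cat(sprintf("  ERD trajectory: beta0 = %g%%, beta1 = %g%%/session, RE SD (%g, %g), rho %g, eps %g\n",
              x$beta0, x$beta1, x$sd_b0, x$sd_b1, x$rho_b, x$sigma_eps))
  cat(sprintf("  Outcome: gamma = (%s), sigma_out = %g\n",
              paste(x$gamma, collapse = ", "), x$sigma_out))
  cat(sprintf("  Artifact rates: %s\n",
              paste(sprintf("%s=%g", names(x$artifact_rates), x$artifact_rates),
                    collapse = ", ")))
  invisible(x)
}

#' Write / read a cohort specification as YAML
#'
#' @param spec a `cohort_spec`.
#' @param path file path.
#' @return `read_cohort_spec` returns a validated `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- unclass(spec)
  ## yaml drops the names of atomic vectors; store named rates as a map
  out$artifact_rates <- as.list(out$artifact_rates)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$artifact_rates <- unlist(raw$artifact_rates)
  raw$gamma <- as.numeric(unlist(raw$gamma))
  raw$trial_timing$iti_range_s <- as.numeric(unlist(raw$trial_timing$iti_range_s))
  do.call(cohort_spec, raw)
}
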