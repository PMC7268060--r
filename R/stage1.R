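#' Stage 1: linear mixed-effects fit of ERD trajectories
#'
#' Fits `erd_percent ~ session + (session | subject)`: a population
#' intercept (mean initial ERD, session index 0-based) and slope (mean ERD
#' change per session) as fixed effects, with correlated per-subject random
#' intercepts and slopes. Sessions may be unequally spaced and subjects may
#' contribute unequal numbers of sessions. Per-subject coefficients are the
#' fixed effects plus the conditional modes (BLUPs) of the random effects.
#'
#' When the correlated random-effects fit is singular the model is refit
#' with independent random effects and the downgrade is recorded.
#'
#' @param erd data frame with columns `subject`, `session` (0-based
#'   numeric) and `erd_percent`; typically one hemisphere and band of an
#'   ERD table.
#' @param reml fit by restricted (default) or full maximum likelihood.
#' @param random_slope fit a per-subject random slope (default) or random
#'   intercepts only (the reduced model of the slope-variance likelihood-
#'   ratio comparison).
#' @return object of class `lmem_fit`: list with `beta0`, `beta1`,
#'   `sd_b0`, `sd_b1`, `corr_b`, `sigma`, `coefficients` (per-subject
#'   `intercept` and `slope`), `logLik`, `reml`, `downgraded`, `n_subjects`
#'   and the underlying `lme4` `model`.
#' @export
fit_stage1 <- function(erd, reml = TRUE, random_slope = TRUE) {
  stopifnot(all(c("subject", "session", "erd_percent") %in% names(erd)))
  erd$subject <- factor(erd$subject)
  if (nlevels(erd$subject) < 2L) stopf("need at least 2 subjects")
  sess_per_subj <- tapply(erd$session, erd$subject, function(s) length(unique(s)))
  if (any(sess_per_subj < 2L)) stopf("every subject needs at least 2 sessions")

  downgraded <- FALSE
  ## calc.derivs = FALSE skips the post-hoc gradient check (and its noisy
  ## near-tolerance warnings) in the many-replicate simulation loops
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  if (random_slope) {
    fit <- suppressMessages(lme4::lmer(
      erd_percent ~ session + (session | subject),
      data = erd, REML = reml, control = ctrl))
    if (lme4::isSingular(fit, tol = 1e-4)) {
      downgraded <- TRUE
      fit <- suppressMessages(lme4::lmer(
        erd_percent ~ session + (session || subject),
        data = erd, REML = reml, control = ctrl))
    }
  } else {
    fit <- suppressMessages(lme4::lmer(
      erd_percent ~ session + (1 | subject),
      data = erd, REML = reml, control = ctrl))
  }
  fe <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  get_vc <- function(v1, v2 = NA) {
    row <- vc$grp != "Residual" & vc$var1 %in% v1 &
      (if (is.na(v2)) is.na(vc$var2) else vc$var2 %in% v2)
    if (any(row)) vc$sdcor[row][1] else NA_real_
  }
  cf <- stats::coef(fit)$subject
  coefficients <- data.frame(subject = rownames(cf),
                             intercept = cf[["(Intercept)"]],
                             slope = cf[["session"]])
  structure(list(beta0 = unname(fe[["(Intercept)"]]),
                 beta1 = unname(fe[["session"]]),
                 sd_b0 = get_vc("(Intercept)"),
                 sd_b1 = get_vc("session"),
                 corr_b = if (downgraded) 0 else get_vc("(Intercept)", "session"),
                 sigma = stats::sigma(fit),
                 coefficients = coefficients,
                 logLik = as.numeric(stats::logLik(fit)),
                 n_par = length(fe) + nrow(vc),
                 reml = reml, downgraded = downgraded,
                 n_subjects = nlevels(erd$subject),
                 model = fit),
            class = "lmem_fit")
}

#' @export
print.lmem_fit <- function(x, ...) {
  cat(sprintf("<lmem_fit> beta0 = %.2f%%, beta1 = %.3f%%/session (%s%s)\n",
              x$beta0, x$beta1, if (x$reml) "REML" else "ML",
              if (x$downgraded) ", independent random effects" else ""))
  cat(sprintf("  RE SD: intercept %.2f, slope %.3f, corr %.2f; residual %.2f; %d subjects\n",
              x$sd_b0, x$sd_b1, x$corr_b, x$sigma, x$n_subjects))
  invisible(x)
}

#' Per-subject trajectories from a stage-1 fit
#'
#' @param fit an `lmem_fit`.
#' @param hemisphere,band labels to attach.
#' @return data frame with `subject`, `hemisphere`, `band`, `intercept`,
#'   `slope`.
#' @export
subject_trajectories <- function(fit, hemisphere = NA_character_,
                                 band = NA_character_) {
  stopifnot(inherits(fit, "lmem_fit"))
  cbind(fit$coefficients[, "subject", drop = FALSE],
        hemisphere = hemisphere, band = band,
        fit$coefficients[, c("intercept", "slope")])
}

#' Likelihood-ratio test between nested mixed models
#'
#' `chisq = 2 * (logLik(full) - logLik(reduced))` on
#' `df = npar(full) - npar(reduced)` degrees of freedom. When the two
#' models differ in their fixed effects and were fit by REML, both are
#' refit by full maximum likelihood first (REML likelihoods are not
#' comparable across different fixed-effects structures).
#'
#' @param full,reduced `lmem_fit` objects, `reduced` nested in `full`.
#' @return list with `chisq`, `df`, `p`.
#' @export
lrt_compare <- function(full, reduced) {
  stopifnot(inherits(full, "lmem_fit"), inherits(reduced, "lmem_fit"))
  get_ll <- function(f) {
    if (f$reml) as.numeric(stats::logLik(
      stats::update(f$model, REML = FALSE))) else f$logLik
  }
  fixed_differ <- !identical(names(lme4::fixef(full$model)),
                             names(lme4::fixef(reduced$model)))
  ll_f <- if (fixed_differ) get_ll(full) else full$logLik
  ll_r <- if (fixed_differ) get_ll(reduced) else reduced$logLik
  if (fixed_differ && (full$reml != reduced$reml))
    warnf("models fit with different objectives; both refit by ML")
  df <- as.integer(full$n_par - reduced$n_par)
  chisq <- 2 * (ll_f - ll_r)
  if (df < 0) stopf("models are not nested: reduced has more parameters")
  if (df == 0L) {
    if (abs(chisq) > 1e-6) stopf("models differ but have equal parameter counts; not nested")
    return(list(chisq = 0, df = 0L, p = 1))
  }
  if (chisq < 0) chisq <- 0
  list(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE))
}
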