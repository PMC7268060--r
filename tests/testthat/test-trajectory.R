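erd_of <- function(cohort, hemi = "ipsilesional")
  cohort$erd[cohort$erd$hemisphere == hemi, ]

test_that("stage 1 recovers exact coefficients in the noiseless limit", {
  spec <- cohort_spec(n_subjects = 8, sessions_per_subject = 6,
                      session_jitter_sd = 0, trial_jitter_sd = 0,
                      sd_b0 = 0, sd_b1 = 0, sigma_eps = 0, seed = 51)
  co <- simulate_cohort(spec)
  fit <- fit_stage1(erd_of(co))
  expect_equal(fit$beta0, spec$beta0, tolerance = 1e-6)
  expect_equal(fit$beta1, spec$beta1, tolerance = 1e-6)
  expect_equal(fit$coefficients$intercept, rep(spec$beta0, 8), tolerance = 1e-4)
})

test_that("conditional modes track per-subject OLS with shrinkage", {
  spec <- cohort_spec(seed = 52, session_jitter_sd = 0, trial_jitter_sd = 0)
  co <- simulate_cohort(spec)
  erd <- erd_of(co)
  fit <- fit_stage1(erd)
  ols <- oracle_ols_trajectories(erd)
  m <- merge(fit$coefficients, ols, by = "subject",
             suffixes = c("_blup", "_ols"))
  expect_gt(cor(m$intercept_blup, m$intercept_ols), 0.9)
  expect_gt(cor(m$slope_blup, m$slope_ols), 0.9)
  ## shrinkage: conditional coefficients are less dispersed than OLS
  expect_lte(var(m$intercept_blup), var(m$intercept_ols))
  expect_lte(var(m$slope_blup), var(m$slope_ols))
  ## per-subject coefficient means are consistent with the fixed effects
  expect_equal(mean(m$intercept_blup), fit$beta0, tolerance = 0.5)
  expect_equal(mean(m$slope_blup), fit$beta1, tolerance = 0.05)
})

test_that("stage 1 validates its inputs", {
  erd1 <- data.frame(subject = "A", session = 0:5, erd_percent = rnorm(6))
  expect_error(fit_stage1(erd1), "2 subjects")
  erd2 <- data.frame(subject = c("A", "A", "B"), session = c(0, 1, 0),
                     erd_percent = rnorm(3))
  expect_error(fit_stage1(erd2), "2 sessions")
})

test_that("stage 2 df identities and coefficient naming", {
  set.seed(53)
  for (n in c(10, 22, 30)) {
    traj <- data.frame(subject = sprintf("S%02d", 1:n),
                       intercept = rnorm(n, -30, 10),
                       slope = rnorm(n, -0.5, 0.4))
    oc <- data.frame(subject = traj$subject, delta = rnorm(n))
    s2 <- fit_stage2(traj, oc)
    expect_equal(s2$df1, 3)
    expect_equal(s2$df2, n - 4)
    expect_equal(s2$df2, s2$n - s2$df1 - 1)     # df identity
    expect_named(s2$coefficients, c("gamma0", "gamma1", "gamma2", "gamma3"))
    expect_lte(s2$adj_r_squared, s2$r_squared)
  }
  expect_error(fit_stage2(data.frame(subject = "A", intercept = 1, slope = 1),
                          data.frame(subject = "A", delta = 1)), "5 subjects")
})

test_that("median split: sign convention, even split, deterministic ties", {
  traj <- data.frame(subject = c("a", "b", "c", "d"),
                     intercept = c(-50, -40, -30, -20))
  sp <- median_split(traj)
  expect_setequal(sp$strong, c("a", "b"))
  expect_setequal(sp$weak, c("c", "d"))

  set.seed(54)
  traj22 <- data.frame(subject = sprintf("S%02d", 1:22),
                       intercept = rnorm(22, -30, 10))
  sp22 <- median_split(traj22)
  expect_length(sp22$strong, 11)
  expect_length(sp22$weak, 11)

  ## duplicates straddling the median are assigned by stable subject order
  tie <- data.frame(subject = c("s1", "s2", "s3", "s4"),
                    intercept = c(-40, -30, -30, -10))
  sp_tie <- median_split(tie)
  expect_identical(sp_tie$strong, c("s1", "s2"))
  expect_identical(sp_tie$weak, c("s3", "s4"))
  expect_error(median_split(tie[1:3, ]), "at least 4")
})

test_that("subgroup regression has df (1, n-2); constant outcome gives F = 0", {
  set.seed(55)
  traj <- data.frame(subject = sprintf("S%02d", 1:11),
                     slope = rnorm(11))
  oc <- data.frame(subject = traj$subject, delta = rnorm(11))
  s <- fit_subgroup_contralesional(traj, oc)
  expect_equal(c(s$df1, s$df2), c(1, 9))
  oc0 <- data.frame(subject = traj$subject, delta = rep(2.5, 11))
  s0 <- fit_subgroup_contralesional(traj, oc0)
  expect_equal(unname(s0$coefficients["gamma_slope"]), 0, tolerance = 1e-10)
  expect_equal(s0$F, 0)
})

test_that("pLC: arithmetic, antisymmetry, translation invariance", {
  ti <- data.frame(subject = c("A", "B"), slope = c(-0.5, -0.1))
  tc <- data.frame(subject = c("A", "B"), slope = c(-0.2, -0.1))
  plc <- compute_plc(ti, tc)
  expect_equal(plc$plc, c(0.3, 0))       # S_H - S_L
  ## swap hemispheres -> sign flips
  expect_equal(compute_plc(tc, ti)$plc, -plc$plc)
  ## adding a constant to both slopes leaves pLC unchanged
  ti2 <- transform(ti, slope = slope + 1.3)
  tc2 <- transform(tc, slope = slope + 1.3)
  expect_equal(compute_plc(ti2, tc2)$plc, plc$plc)
  expect_error(compute_plc(ti, tc[1, , drop = FALSE]), "both hemispheres")
})

test_that("pLC regression: df (1, 20) at n = 22; degenerate design errors", {
  set.seed(56)
  plc <- data.frame(subject = sprintf("S%02d", 1:22), plc = rnorm(22))
  oc <- data.frame(subject = plc$subject, delta = rnorm(22))
  f <- fit_plc_regression(plc, oc)
  expect_equal(c(f$df1, f$df2), c(1, 20))
  plc0 <- transform(plc, plc = 0.7)
  expect_error(fit_plc_regression(plc0, oc), "degenerate")
})

test_that("likelihood-ratio comparison: identical models give chisq 0, p 1", {
  spec <- cohort_spec(n_subjects = 10, sessions_per_subject = 8,
                      session_jitter_sd = 0, seed = 57)
  co <- simulate_cohort(spec)
  f <- fit_stage1(erd_of(co), reml = FALSE)
  res <- lrt_compare(f, f)
  expect_equal(res$chisq, 0)
  expect_equal(res$df, 0L)
  expect_equal(res$p, 1)
})

test_that("random-slope variance is detected by the LRT when present", {
  spec <- cohort_spec(n_subjects = 20, sessions_per_subject = 12,
                      session_jitter_sd = 0, sd_b1 = 1.5, sigma_eps = 4,
                      seed = 58)
  co <- simulate_cohort(spec)
  full <- fit_stage1(erd_of(co), reml = FALSE)
  reduced <- fit_stage1(erd_of(co), reml = FALSE, random_slope = FALSE)
  res <- lrt_compare(full, reduced)
  expect_equal(res$df, 2L)            # slope variance + correlation
  expect_lt(res$p, 0.001)
  expect_error(lrt_compare(reduced, full), "not nested")

  ## without slope variance the evidence is weak far more often: just check
  ## chisq is finite and nonnegative on a null cohort
  spec0 <- cohort_spec(n_subjects = 20, sessions_per_subject = 12,
                       session_jitter_sd = 0, sd_b1 = 0, sigma_eps = 4,
                       seed = 59)
  co0 <- simulate_cohort(spec0)
  full0 <- fit_stage1(erd_of(co0), reml = FALSE)
  red0 <- fit_stage1(erd_of(co0), reml = FALSE, random_slope = FALSE)
  res0 <- lrt_compare(full0, red0)
  expect_gte(res0$chisq, 0)
  expect_gt(res0$p, res$p)
})

test_that("two-stage pipeline recovers the full gamma sign pattern", {
  ## strong-signal regime fixed by the design-time power analysis (vignette)
  n_rep <- 50
  truth <- sign(cohort_spec()$gamma)
  hits <- vapply(seq_len(n_rep), function(s) {
    spec <- cohort_spec(sigma_eps = 1, sigma_out = 0.25,
                        session_jitter_sd = 0, trial_jitter_sd = 0,
                        seed = 1000 + s)
    co <- simulate_cohort(spec)
    f1 <- fit_stage1(co$erd[co$erd$hemisphere == "ipsilesional", ])
    s2 <- fit_stage2(subject_trajectories(f1), co$outcomes)
    all(sign(unname(s2$coefficients)) == truth)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("delta_cfma validates the 0-54 scale", {
  d <- delta_cfma("A", 10, 12, 15)
  expect_equal(d$delta, 4)
  expect_error(delta_cfma("A", -1, 12, 15), "0, 54")
  expect_error(delta_cfma("A", 10, 12, 60), "0, 54")
})
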