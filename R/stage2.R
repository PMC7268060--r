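#' Clinical change scores
#'
#' Builds the `DeltaCFMA` table: the clinical change is the post score minus
#' the mean of the two baseline scores of the combined upper-limb
#' Fugl-Meyer assessment (0-54 scale).
#'
#' @param subject subject identifiers.
#' @param baseline1,baseline2,post cFMA scores in `[0, 54]`.
#' @return data frame with `subject`, the three scores and `delta`.
#' @export
delta_cfma <- function(subject, baseline1, baseline2, post) {
  scores <- c(baseline1, baseline2, post)
  if (any(scores < 0 | scores > 54))
    stopf("cFMA scores must lie in [0, 54]")
  data.frame(subject = subject, baseline1 = baseline1,
             baseline2 = baseline2, post = post,
             delta = post - (baseline1 + baseline2) / 2)
}

new_stage2_result <- function(model, coef_names) {
  co <- stats::coef(model)
  names(co) <- coef_names
  y <- stats::model.response(stats::model.frame(model))
  n_obs <- length(y)
  ## degrees of freedom are structural (df1 = number of predictors,
  ## df2 = n - df1 - 1) even when a predictor is aliased at this sample:
  ## an aliased column (NA coefficient) contributes nothing to the fit but
  ## is still part of the declared model
  df1 <- length(co) - 1L
  df2 <- n_obs - df1 - 1L
  rss <- sum(stats::resid(model)^2)
  tss <- sum((y - mean(y))^2)
  degenerate <- tss <= 1e-12 * max(1, mean(y)^2)
  f_val <- if (degenerate || df2 <= 0) 0
           else ((tss - rss) / df1) / (rss / df2)
  if (!is.finite(f_val)) f_val <- 0
  r2 <- if (degenerate) 0 else 1 - rss / tss
  structure(list(coefficients = co,
                 F = f_val, df1 = df1, df2 = df2,
                 p = stats::pf(f_val, df1, df2, lower.tail = FALSE),
                 r_squared = r2,
                 adj_r_squared = 1 - (1 - r2) * (n_obs - 1) / df2,
                 n = n_obs,
                 model = model),
            class = "stage2_result")
}

#' @export
print.stage2_result <- function(x, ...) {
  cat(sprintf("<stage2_result> F(%d, %d) = %.3f, p = %.4g, adj r2 = %.3f\n",
              x$df1, x$df2, x$F, x$p, x$adj_r_squared))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Stage 2: regression of clinical change on ERD trajectory coefficients
#'
#' Ordinary least-squares fit of
#' `delta ~ intercept + slope + intercept:slope` across subjects, using the
#' per-subject coefficients of the stage-1 mixed model as predictors
#' (uncentered, so the interaction is interpreted on the raw ERD scale).
#' The overall F test has `(3, n - 4)` degrees of freedom.
#'
#' @param trajectories data frame from [subject_trajectories()] (columns
#'   `subject`, `intercept`, `slope`), one row per subject.
#' @param outcomes data frame with `subject` and `delta` (e.g. from
#'   [delta_cfma()]).
#' @return a `stage2_result` with coefficients
#'   `(gamma0, gamma1, gamma2, gamma3)` for intercept, initial-ERD effect,
#'   slope effect and interaction.
#' @export
fit_stage2 <- function(trajectories, outcomes) {
  df <- merge(trajectories, outcomes[, c("subject", "delta")], by = "subject")
  if (nrow(df) != nrow(trajectories))
    stopf("outcomes missing for %d subject(s)",
          nrow(trajectories) - nrow(df))
  if (nrow(df) <= 5L) stopf("need more than 5 subjects for the stage-2 model")
  X <- stats::model.matrix(~ intercept * slope, df)
  if (kappa(X) > 1e10)
    warnf("stage-2 design is ill-conditioned (collinear predictors)")
  model <- stats::lm(delta ~ intercept * slope, data = df)
  new_stage2_result(model, c("gamma0", "gamma1", "gamma2", "gamma3"))
}

#' Median split of subjects by initial ERD
#'
#' More negative ERD means stronger desynchronization, so subjects below
#' the median of the split key form the "strong" group and subjects above
#' it the "weak" group. With an even subject count the groups are equal;
#' ties straddling the median are assigned deterministically by stable
#' (key, subject) order.
#'
#' @param trajectories data frame with `subject` and the split key column.
#' @param key column to split on (default `"intercept"`, the initial ERD).
#' @return list with `strong` and `weak` subject-id vectors and `median`.
#' @export
median_split <- function(trajectories, key = "intercept") {
  stopifnot(key %in% names(trajectories))
  n <- nrow(trajectories)
  if (n < 4L) stopf("need at least 4 subjects for a median split")
  k <- trajectories[[key]]
  med <- stats::median(k)
  ord <- order(k, trajectories$subject)            # stable tie-break
  n_strong <- if (n %% 2L == 0L) n %/% 2L else sum(k < med)
  strong <- trajectories$subject[ord[seq_len(n_strong)]]
  weak <- setdiff(trajectories$subject[ord], strong)
  list(strong = strong, weak = weak, median = med)
}

#' Subgroup regression of clinical change on the contralesional slope
#'
#' Simple regression `delta ~ slope` within one median-split subgroup,
#' using the contralesional (healthy-hemisphere) ERD slope as predictor;
#' F test on `(1, n - 2)` degrees of freedom.
#'
#' @param trajectories contralesional [subject_trajectories()] rows for the
#'   subgroup's subjects.
#' @param outcomes data frame with `subject` and `delta`.
#' @return a `stage2_result` with coefficients `(gamma0, gamma_slope)`.
#' @export
fit_subgroup_contralesional <- function(trajectories, outcomes) {
  df <- merge(trajectories, outcomes[, c("subject", "delta")], by = "subject")
  if (nrow(df) < 3L) stopf("subgroup too small (need >= 3 subjects)")
  model <- stats::lm(delta ~ slope, data = df)
  new_stage2_result(model, c("gamma0", "gamma_slope"))
}

#' Progressive laterality coefficient
#'
#' `pLC = S_H - S_L`: the contralesional (healthy-hemisphere) ERD slope
#' minus the ipsilesional one. Positive values mean that desynchronization
#' became progressively stronger (more negative slope) on the lesioned
#' hemisphere relative to the healthy one.
#'
#' @param trajectories_ipsi,trajectories_contra per-subject trajectory
#'   tables (columns `subject`, `slope`) for the two hemispheres.
#' @return data frame with `subject` and `plc`.
#' @export
compute_plc <- function(trajectories_ipsi, trajectories_contra) {
  df <- merge(trajectories_ipsi[, c("subject", "slope")],
              trajectories_contra[, c("subject", "slope")],
              by = "subject", suffixes = c("_ipsi", "_contra"))
  if (nrow(df) < nrow(trajectories_ipsi) ||
      nrow(df) < nrow(trajectories_contra))
    stopf("both hemispheres must be fitted for every subject")
  data.frame(subject = df$subject, plc = df$slope_contra - df$slope_ipsi)
}

#' Regression of clinical change on the progressive laterality coefficient
#'
#' Simple regression `delta ~ pLC`, F test on `(1, n - 2)` degrees of
#' freedom.
#'
#' @param plc data frame from [compute_plc()].
#' @param outcomes data frame with `subject` and `delta`.
#' @return a `stage2_result` with coefficients `(gamma0, gamma_plc)`.
#' @export
fit_plc_regression <- function(plc, outcomes) {
  df <- merge(plc, outcomes[, c("subject", "delta")], by = "subject")
  if (nrow(df) < 3L) stopf("need at least 3 subjects")
  if (stats::var(df$plc) == 0)
    stopf("degenerate design: all pLC values are equal")
  model <- stats::lm(delta ~ plc, data = df)
  new_stage2_result(model, c("gamma0", "gamma_plc"))
}
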