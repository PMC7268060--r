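#' Pipeline run configuration
#'
#' @param source `"synthetic"` (generate a cohort from `cohort`) or
#'   `"directory"` (read recordings from `data_dir`; EDF/BrainVision files
#'   named `<subject>_ses<k>.<ext>`).
#' @param cohort a [cohort_spec()] (synthetic source).
#' @param signal `"erd"` or `"raw"` signal level for synthetic cohorts; at
#'   the `"erd"` level the artifact-rejection and spectral stages are
#'   skipped (the generator emits session ERD directly).
#' @param data_dir input directory for `source = "directory"`.
#' @param rejection a [rejection_config()].
#' @param bands list of [band_definition()]s to analyse.
#' @param erd_method `"trialwise"` or `"pooled"` (see [compute_erd()]).
#' @param reml stage-1 fitting objective.
#' @param out_dir output directory for the result bundle.
#' @param seed integer seed recorded in every output (overrides the cohort
#'   spec's seed for synthetic runs).
#' @return object of class `run_config`.
#' @export
run_config <- function(source = c("synthetic", "directory"),
                       cohort = cohort_spec(),
                       signal = c("erd", "raw"),
                       data_dir = NULL,
                       rejection = rejection_config(),
                       bands = list(alpha_band()),
                       erd_method = "trialwise",
                       reml = TRUE,
                       out_dir = tempfile("erdtraj_run_"),
                       seed = NULL) {
  source <- match.arg(source)
  signal <- match.arg(signal)
  if (source == "directory" && (is.null(data_dir) || !dir.exists(data_dir)))
    stopf("data_dir must exist for source = \"directory\"")
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(list(source = source, cohort = cohort, signal = signal,
                 data_dir = data_dir, rejection = rejection, bands = bands,
                 erd_method = erd_method, reml = reml,
                 out_dir = out_dir, seed = seed %||% cohort$seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized top-level keys: `source`, `signal`, `data_dir`, `out_dir`,
#' `seed`, `erd_method`, `reml`, plus nested `cohort` (fields of
#' [cohort_spec()]), `rejection` (fields of [rejection_config()]) and
#' `bands` (list of `{name, f_lo, f_hi}`).
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  cohort <- if (!is.null(y$cohort)) {
    y$cohort$artifact_rates <- unlist(y$cohort$artifact_rates)
    if (!is.null(y$cohort$gamma)) y$cohort$gamma <- as.numeric(unlist(y$cohort$gamma))
    if (!is.null(y$cohort$trial_timing))
      y$cohort$trial_timing$iti_range_s <-
        as.numeric(unlist(y$cohort$trial_timing$iti_range_s))
    do.call(cohort_spec, y$cohort)
  } else cohort_spec()
  rejection <- if (!is.null(y$rejection)) do.call(rejection_config, y$rejection)
               else rejection_config()
  bands <- if (!is.null(y$bands))
    lapply(y$bands, function(b) band_definition(b$name, b$f_lo, b$f_hi))
  else list(alpha_band())
  run_config(source = y$source %||% "synthetic",
             cohort = cohort, signal = y$signal %||% "erd",
             data_dir = y$data_dir, rejection = rejection, bands = bands,
             erd_method = y$erd_method %||% "trialwise",
             reml = y$reml %||% TRUE,
             out_dir = y$out_dir %||% tempfile("erdtraj_run_"),
             seed = y$seed)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort generation or data loading, epoching,
#' artifact rejection (ICA ocular cleaning + trial detectors + exclusion
#' rules), ERD extraction per hemisphere and band, the stage-1 mixed model,
#' the stage-2 outcome regression with interaction, the median-split
#' contralesional subgroup models, and the pLC regression. All artifacts
#' are serialized into `config$out_dir` together with a `MANIFEST.json`;
#' a failure in any stage writes the manifest with the failed stage and
#' rethrows the error.
#'
#' @param config a [run_config()].
#' @return invisible list (the result bundle): `erd`, `rejection`,
#'   `stage1` (per hemisphere), `stage2`, `subgroups`, `plc_fit`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, status = "incomplete",
                   stage = NA_character_, files = character())
  bundle <- list(out_dir = config$out_dir)
  write_manifest <- function()
    jsonlite::write_json(manifest, file.path(config$out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE, digits = NA)
  stage <- function(name, expr) {
    manifest$stage <<- name
    write_manifest()
    tryCatch(expr, error = function(e) {
      manifest$status <<- sprintf("failed at stage '%s'", name)
      write_manifest()
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  add_file <- function(path) manifest$files <<- c(manifest$files, basename(path))

  inputs <- stage("input", pipeline_inputs(config))
  bundle$outcomes <- inputs$outcomes

  if (!is.null(inputs$sessions)) {
    rej <- stage("artifact_rejection", {
      reports <- list()
      clean_epochs <- list()
      for (item in inputs$sessions) {
        ep <- item$epochs
        fl <- flag_trials(ep, config$rejection)
        fl <- cbind(subject = ep$subject_id, session = ep$session_index, fl)
        reports[[length(reports) + 1L]] <- fl
        clean_epochs[[length(clean_epochs) + 1L]] <-
          list(epochs = subset_epochs(ep, !fl$removed),
               subject = ep$subject_id, session = ep$session_index)
      }
      report <- apply_exclusions(do.call(rbind, reports), config$rejection)
      for (f in write_rejection_report(report, config$out_dir)) add_file(f)
      list(report = report, clean = clean_epochs)
    })
    bundle$rejection <- rej$report

    erd <- stage("erd_extraction", {
      excluded_sessions <- rej$report$sessions[rej$report$sessions$excluded, ]
      excluded_subjects <- rej$report$subjects$subject[rej$report$subjects$excluded]
      rows <- list()
      for (item in rej$clean) {
        if (item$subject %in% excluded_subjects) next
        if (nrow(excluded_sessions) && any(
          excluded_sessions$subject == item$subject &
          excluded_sessions$session == item$session)) next
        if (!length(item$epochs$trials)) next
        rows[[length(rows) + 1L]] <-
          erd_samples(item$epochs, bands = config$bands,
                      method = config$erd_method)
      }
      out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(subject = character(), session_index = integer(),
                   hemisphere = character(), band = character(),
                   erd_percent = numeric(), n_trials_used = integer())
      names(out)[names(out) == "session_index"] <- "session"
      add_file(write_erd_samples(out, file.path(config$out_dir, "erd_samples.tsv")))
      out
    })
  } else {
    erd <- inputs$erd
    add_file(write_erd_samples(erd, file.path(config$out_dir, "erd_samples.tsv")))
  }
  bundle$erd <- erd

  models <- stage("stage1", {
    fits <- list()
    if (is.null(erd) || !nrow(erd))
      stopf("insufficient subjects (0) for the mixed model")
    for (b in unique(erd$band)) {
      for (h in c("ipsilesional", "contralesional")) {
        sub <- erd[erd$band == b & erd$hemisphere == h, ]
        if (!nrow(sub)) next
        if (length(unique(sub$subject)) < 6L)
          stopf("insufficient subjects (%d) for the mixed model",
                length(unique(sub$subject)))
        fits[[paste(b, h, sep = "_")]] <- fit_stage1(sub, reml = config$reml)
      }
    }
    fits
  })
  bundle$stage1 <- models

  bundle <- stage("stage2", {
    primary_band <- config$bands[[1]]$name
    traj_i <- subject_trajectories(models[[paste(primary_band, "ipsilesional", sep = "_")]],
                                   "ipsilesional", primary_band)
    traj_c <- subject_trajectories(models[[paste(primary_band, "contralesional", sep = "_")]],
                                   "contralesional", primary_band)
    s2 <- fit_stage2(traj_i, inputs$outcomes)
    split <- median_split(traj_i)
    subgroups <- lapply(list(strong = split$strong, weak = split$weak),
                        function(ids) fit_subgroup_contralesional(
                          traj_c[traj_c$subject %in% ids, ], inputs$outcomes))
    plc <- compute_plc(traj_i, traj_c)
    plc_fit <- fit_plc_regression(plc, inputs$outcomes)

    results <- list(
      seed = config$seed,
      stage1 = lapply(models, function(f)
        f[c("beta0", "beta1", "sd_b0", "sd_b1", "corr_b", "sigma",
            "logLik", "reml", "downgraded", "n_subjects")]),
      stage2 = stage2_to_list(s2),
      subgroups = c(lapply(subgroups, stage2_to_list),
                    list(median = split$median)),
      plc = stage2_to_list(plc_fit))
    jsonlite::write_json(results, file.path(config$out_dir, "models.json"),
                         auto_unbox = TRUE, digits = NA)
    add_file("models.json")
    traj <- rbind(traj_i, traj_c)
    utils::write.table(merge(traj, plc, by = "subject", all.x = TRUE),
                       file.path(config$out_dir, "subject_coefficients.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    add_file("subject_coefficients.tsv")
    plot_pipeline_figures(config$out_dir, traj_i, traj_c, plc,
                          inputs$outcomes, split, add_file)
    c(bundle, list(stage2 = s2, subgroups = subgroups, split = split,
                   plc = plc, plc_fit = plc_fit))
  })

  manifest$status <- "complete"
  manifest$stage <- "done"
  write_manifest()
  invisible(bundle)
}

stage2_to_list <- function(x)
  list(coefficients = as.list(x$coefficients), F = x$F, df1 = x$df1,
       df2 = x$df2, p = x$p, r_squared = x$r_squared,
       adj_r_squared = x$adj_r_squared, n = x$n)

pipeline_inputs <- function(config) {
  if (config$source == "synthetic") {
    cohort <- simulate_cohort(config$cohort, signal = config$signal)
    sessions <- NULL
    if (config$signal == "raw") {
      sessions <- list()
      for (sid in names(cohort$sessions))
        for (ses in cohort$sessions[[sid]])
          sessions[[length(sessions) + 1L]] <- list(epochs = session_to_epochs(ses))
    }
    list(erd = cohort$erd, outcomes = cohort$outcomes, sessions = sessions,
         cohort = cohort)
  } else {
    files <- list.files(config$data_dir, pattern = "\\.(edf|vhdr)$",
                        full.names = TRUE)
    if (!length(files)) stopf("no EDF/BrainVision recordings in %s", config$data_dir)
    sessions <- lapply(files, function(f)
      list(epochs = epoch_trials(read_recording(f))))
    outcomes_path <- file.path(config$data_dir, "outcomes.tsv")
    if (!file.exists(outcomes_path))
      stopf("outcomes.tsv with cFMA scores required in %s", config$data_dir)
    oc <- utils::read.table(outcomes_path, header = TRUE, sep = "\t")
    list(erd = NULL, outcomes = oc, sessions = sessions)
  }
}

plot_pipeline_figures <- function(out_dir, traj_i, traj_c, plc, outcomes,
                                  split, add_file) {
  merged <- merge(traj_i, outcomes[, c("subject", "delta")], by = "subject")
  plc_m <- merge(plc, outcomes[, c("subject", "delta")], by = "subject")
  open_dev <- function(path) {
    ok <- tryCatch({ grDevices::svg(path, width = 7, height = 5); TRUE },
                   error = function(e) FALSE)
    if (!ok) ok <- tryCatch({ grDevices::pdf(sub("\\.svg$", ".pdf", path),
                                             width = 7, height = 5); TRUE },
                            error = function(e) FALSE)
    ok
  }
  scatter_fit <- function(x, y, xlab, main) {
    graphics::plot(x, y, pch = 19, xlab = xlab, ylab = "Delta cFMA", main = main)
    if (length(unique(x)) > 1) graphics::abline(stats::lm(y ~ x), lty = 2)
  }
  fig <- function(name, fun) {
    path <- file.path(out_dir, name)
    if (open_dev(path)) {
      on.exit(grDevices::dev.off(), add = TRUE)
      fun()
      add_file(name)
    }
  }
  fig("fig_stage2_subgroups.svg", function() {
    graphics::par(mfrow = c(1, 2))
    for (grp in c("strong", "weak")) {
      sel <- merged$subject %in% split[[grp]]
      scatter_fit(merged$slope[sel], merged$delta[sel],
                  "ipsilesional ERD slope (%/session)",
                  sprintf("%s initial ERD", grp))
    }
  })
  fig("fig_contralesional.svg", function() {
    m2 <- merge(traj_c, outcomes[, c("subject", "delta")], by = "subject")
    sel <- m2$subject %in% split$weak
    scatter_fit(m2$slope[sel], m2$delta[sel],
                "contralesional ERD slope (%/session)",
                "weak-initial-ERD subgroup")
  })
  fig("fig_plc.svg", function()
    scatter_fit(plc_m$plc, plc_m$delta, "pLC (%/session)",
                "progressive laterality coefficient"))
}

#' Render a human-readable report of a pipeline run
#'
#' @param bundle_dir output directory of a completed [run_pipeline()] run.
#' @return path of the written `report.md`, invisibly.
#' @export
make_report <- function(bundle_dir) {
  manifest_path <- file.path(bundle_dir, "MANIFEST.json")
  if (!file.exists(manifest_path)) stopf("no MANIFEST.json in %s", bundle_dir)
  manifest <- jsonlite::read_json(manifest_path)
  missing <- setdiff(c("models.json", "erd_samples.tsv"),
                     list.files(bundle_dir))
  if (!identical(manifest$status, "complete") || length(missing))
    stopf("bundle incomplete (status '%s'%s)", manifest$status,
          if (length(missing)) paste0("; missing: ",
                                      paste(missing, collapse = ", ")) else "")
  models <- jsonlite::read_json(file.path(bundle_dir, "models.json"))
  erd <- utils::read.table(file.path(bundle_dir, "erd_samples.tsv"),
                           header = TRUE, sep = "\t")
  lines <- c("# ERD trajectory analysis report", "",
             sprintf("Seed: %s", manifest$seed), "")
  if (!nrow(erd) || !length(unique(erd$band))) {
    lines <- c(lines, "No bands analyzed.")
  } else {
    n_subj <- length(unique(erd$subject))
    lines <- c(lines,
               sprintf("Subjects analysed: %d; ERD samples: %d (bands: %s)",
                       n_subj, nrow(erd), paste(unique(erd$band), collapse = ", ")),
               "")
    rej_path <- file.path(bundle_dir, "rejection_summary.json")
    if (file.exists(rej_path)) {
      rs <- jsonlite::read_json(rej_path)
      n_excl_ses <- sum(vapply(rs$sessions, function(s) isTRUE(s$excluded), TRUE))
      n_excl_sub <- sum(vapply(rs$subjects, function(s) isTRUE(s$excluded), TRUE))
      lines <- c(lines, "## Artifact rejection",
                 sprintf("Sessions excluded: %d; subjects excluded: %d",
                         n_excl_ses, n_excl_sub), "")
    }
    s2 <- models$stage2
    lines <- c(lines, "## Stage-2 interaction model",
               sprintf("F(%d, %d) = %.3f, p = %.4g, adjusted r2 = %.3f",
                       s2$df1, s2$df2, s2$F, s2$p, s2$adj_r_squared), "",
               "## Median-split contralesional subgroup models",
               sprintf("median initial ERD: %.2f%%", models$subgroups$median))
    for (grp in c("strong", "weak")) {
      g <- models$subgroups[[grp]]
      lines <- c(lines, sprintf("- %s: F(%d, %d) = %.3f, p = %.4g", grp,
                                g$df1, g$df2, g$F, g$p))
    }
    pl <- models$plc
    lines <- c(lines, "", "## Progressive laterality coefficient",
               sprintf("F(%d, %d) = %.3f, p = %.4g, adjusted r2 = %.3f",
                       pl$df1, pl$df2, pl$F, pl$p, pl$adj_r_squared))
  }
  path <- file.path(bundle_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
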