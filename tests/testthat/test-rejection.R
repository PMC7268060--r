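clean_session <- function(n_trials = 12, seed = 31, spec = tiny_spec()) {
  set.seed(seed)
  simulate_session(spec, -30, n_trials = n_trials)
}

test_that("waveform_length matches closed-form values", {
  expect_equal(waveform_length(rep(5, 100), 0.1, 100), rep(0, 10))
  n <- 20
  alt <- rep(c(1, -1), length.out = n)
  expect_equal(waveform_length(alt, n / 100, 100), 2 * (n - 1))
  ramp <- seq(0, 1, length.out = 50)
  expect_equal(waveform_length(ramp, 0.5, 100), 1)
  ## two windows are scored independently
  expect_equal(waveform_length(c(ramp, ramp), 0.5, 100), c(1, 1))
  expect_error(waveform_length(numeric(0), 0.1, 100), "empty")
  expect_error(waveform_length(rnorm(10), 1, 100), "shorter")
})

test_that("high-frequency bursts are detected and thresholding is strict", {
  ses <- clean_session(10)
  ses_inj <- inject_artifacts(ses, c(hf = 1))
  ep <- session_to_epochs(ses_inj)
  d <- detect_hf_emg(ep)
  expect_true(all(d$flag))

  ## strict ">": a threshold equal to the maximum statistic flags nothing
  cfg_eq <- rejection_config(hf_z_threshold = max(d$stat))
  expect_false(any(detect_hf_emg(ep, cfg_eq)$flag))
  cfg_lt <- rejection_config(hf_z_threshold = max(d$stat) * 0.999)
  expect_true(any(detect_hf_emg(ep, cfg_lt)$flag))

  expect_error(detect_hf_emg(session_to_epochs(
    clean_session(2, spec = tiny_spec(fs = 250)))), "too low")
})

test_that("hf false-flag rate on Gaussian sessions matches a Monte-Carlo oracle", {
  ## small synthetic geometry so the oracle is cheap: 6 channels, 1 s trials
  set.seed(32)
  fs <- 500; nch <- 6; nsamp <- 500; n_trials <- 120
  mk_epochs <- function(n_trials) {
    trials <- lapply(seq_len(n_trials), function(i) {
      x <- matrix(rnorm(nch * nsamp), nch,
                  dimnames = list(paste0("C", 1:nch), NULL))
      list(trial = i, rest = x[, 1:200, drop = FALSE],
           prep = x[, 201:300, drop = FALSE],
           move = x[, 301:500, drop = FALSE])
    })
    structure(list(trials = trials, fs = fs,
                   channel_labels = paste0("C", 1:nch),
                   channel_kinds = setNames(rep("EEG", nch), paste0("C", 1:nch)),
                   subject_id = "X", session_index = 0L, lesion_side = "left",
                   dropped = data.frame()), class = "erd_epochs")
  }
  ep <- mk_epochs(n_trials)
  d <- detect_hf_emg(ep)
  observed <- mean(d$flag)

  ## oracle: same statistic recomputed independently on fresh noise,
  ## using population z-scoring (the session estimate converges to it)
  n_rep <- 400
  stats_null <- vapply(seq_len(n_rep), function(i) {
    x <- matrix(rnorm(nch * nsamp), nch)
    xf <- t(apply(x, 1, oracle_bandpass, fs = fs, lo = 110, hi = 140))
    sd0 <- apply(xf, 1, sd)
    oracle_trial_zstat(xf, rep(0, nch), sd0)
  }, 0)
  p_oracle <- mean(stats_null > 4)
  tol <- 2.58 * sqrt(p_oracle * (1 - p_oracle) * (1 / n_trials + 1 / n_rep)) + 0.02
  expect_lt(abs(observed - p_oracle), tol)
})

test_that("offset jumps are detected; clean trials never reach 20 SDs", {
  ses <- clean_session(20, seed = 33)
  ep0 <- session_to_epochs(ses)
  d0 <- detect_offset(ep0)
  expect_false(any(d0$flag))       # P(|z| > 20) is numerically zero

  ## sparse 25-SD cap-shift on every EEG channel of one trial: the session
  ## statistics stay essentially clean so the jump towers over threshold
  ses1 <- ses
  tr <- ses1$trials[[7]]
  eeg <- setdiff(rownames(tr$move),
                 grep("^EOG|^EMG", rownames(tr$move), value = TRUE))
  for (ch in eeg) {
    s <- sd(c(tr$iti[ch, ], tr$prep[ch, ], tr$move[ch, ]))
    tr$move[ch, 500:ncol(tr$move)] <- tr$move[ch, 500:ncol(tr$move)] + 25 * s
  }
  ses1$trials[[7]] <- tr
  d1 <- detect_offset(session_to_epochs(ses1))
  expect_true(d1$flag[7])
  expect_false(any(d1$flag[-7]))

  ## z-scores are scale invariant: scaling the whole session leaves the
  ## statistic unchanged
  ses_scaled <- ses1
  ses_scaled$trials <- lapply(ses1$trials, function(tr) {
    tr$iti <- tr$iti * 0.5; tr$prep <- tr$prep * 0.5; tr$move <- tr$move * 0.5
    tr
  })
  d_scaled <- detect_offset(session_to_epochs(ses_scaled))
  expect_equal(d_scaled$stat, d1$stat, tolerance = 1e-10)
  expect_identical(d_scaled$flag, d1$flag)
})

test_that("EMG rule: paretic-rest and healthy-move flag, healthy-rest does not", {
  spec <- tiny_spec()
  set.seed(34)
  ses <- simulate_session(spec, -30, n_trials = 10, lesion_side = "left")
  ## lesion left => paretic arm right, healthy arm left
  burst <- function(x, ch, idx, sd_mult = 10)
    { x[ch, idx] <- x[ch, idx] + sd_mult * sd(x[ch, ]) * rnorm(length(idx)); x }
  n_iti <- ncol(ses$trials[[1]]$iti)
  rest_idx <- (n_iti - 900):(n_iti - 700)      # inside last 4 s of ITI
  ## trial 1: paretic (right) burst in rest
  ses$trials[[1]]$iti <- burst(ses$trials[[1]]$iti, "EMG_BIC_R", rest_idx)
  ## trial 2: healthy (left) burst during movement
  ses$trials[[2]]$move <- burst(ses$trials[[2]]$move, "EMG_ECU_L", 300:500)
  ## trial 3: healthy burst during rest -- allowed, not a removal criterion
  ses$trials[[3]]$iti <- burst(ses$trials[[3]]$iti, "EMG_ED_L", rest_idx)
  ## trial 4: paretic burst during movement -- the trained movement, allowed
  ses$trials[[4]]$move <- burst(ses$trials[[4]]$move, "EMG_TRI_R", 300:500)
  ## raise the threshold above the Gaussian-noise null so only the planted
  ## 10x bursts can flag (the nominal-threshold null rate is checked against
  ## its Monte-Carlo oracle elsewhere)
  d <- detect_emg_movement(session_to_epochs(ses),
                           rejection_config(emg_wl_sd_threshold = 6))
  expect_true(d$flag_rest_paretic[1])
  expect_true(d$flag_move_healthy[2])
  expect_false(d$flag[3])
  expect_false(d$flag[4])
})

test_that("flat EMG yields no contraction flags", {
  ses <- clean_session(4, seed = 35)
  for (i in seq_along(ses$trials)) {
    for (ph in c("iti", "prep", "move")) {
      m <- ses$trials[[i]][[ph]]
      m[grep("^EMG", rownames(m)), ] <- 0
      ses$trials[[i]][[ph]] <- m
    }
  }
  d <- detect_emg_movement(session_to_epochs(ses))
  expect_false(any(d$flag))
})

test_that("detectors are deterministic and monotone in their threshold", {
  ses <- inject_artifacts(clean_session(8, seed = 36), c(hf = 0.5, offset = 0.2))
  ep <- session_to_epochs(ses)
  expect_identical(detect_hf_emg(ep)$flag, detect_hf_emg(ep)$flag)
  f1 <- flag_trials(ep)
  f2 <- flag_trials(ep)
  expect_identical(f1, f2)
  base_stat <- detect_hf_emg(ep)$stat
  for (thr in c(2, 4, 6, 10)) {
    hi <- detect_hf_emg(ep, rejection_config(hf_z_threshold = thr + 1))$flag
    lo <- detect_hf_emg(ep, rejection_config(hf_z_threshold = thr))$flag
    expect_flag_subset(hi, lo)
  }
})

test_that("ocular components are identified and removed", {
  set.seed(37)
  ses <- simulate_session(tiny_spec(), -30, n_trials = 6)
  ses <- inject_artifacts(ses, c(eog = 1))
  rec <- session_to_recording(ses)
  res <- remove_eog(rec)
  expect_gte(length(res$removed_components), 1L)
  blink <- rec$samples["EOGv", ]
  for (ch in c("Fp1", "Fp2"))
    expect_lt(abs(cor(res$recording$samples[ch, ], blink)), 0.1)
  ## EOG channels themselves untouched
  expect_identical(res$recording$samples["EOGv", ], rec$samples["EOGv", ])
  ## determinism of the seeded decomposition
  res2 <- remove_eog(rec)
  expect_identical(res$removed_components, res2$removed_components)
  expect_equal(res$recording$samples, res2$recording$samples)
})

test_that("flat EOG removes nothing; rank-deficient EEG errors", {
  set.seed(38)
  ses <- simulate_session(tiny_spec(), -30, n_trials = 3)
  rec <- session_to_recording(ses)
  rec$samples["EOGv", ] <- 0
  rec$samples["EOGh", ] <- 0
  res <- remove_eog(rec)
  expect_length(res$removed_components, 0L)
  expect_identical(res$recording$samples, rec$samples)

  rec2 <- session_to_recording(ses)
  rec2$samples["Fp2", ] <- rec2$samples["Fp1", ]   # duplicated channel
  expect_error(remove_eog(rec2), "rank deficient")
  rec3 <- session_to_recording(ses)
  rec3$samples <- rec3$samples[setdiff(rownames(rec3$samples),
                                       c("EOGv", "EOGh")), ]
  rec3$channel_kinds <- rec3$channel_kinds[rownames(rec3$samples)]
  rec3$channel_labels <- rownames(rec3$samples)
  expect_error(remove_eog(rec3), "EOG")
})

test_that("two distinct ocular sources are both reported", {
  set.seed(39)
  ses <- simulate_session(tiny_spec(), -30, n_trials = 6)
  rec <- session_to_recording(ses)
  n <- ncol(rec$samples)
  t_s <- seq_len(n) / rec$fs
  ## blink train (vertical) and slow saccade drift (horizontal), independent
  blink <- 150 * pmax(0, sin(2 * pi * 0.4 * t_s))^8
  sacc <- 80 * sign(sin(2 * pi * 0.15 * t_s + 1))
  sacc <- stats::filter(sacc, rep(1 / 50, 50), sides = 2)
  sacc[is.na(sacc)] <- 0
  rec$samples["EOGv", ] <- rec$samples["EOGv", ] + blink
  rec$samples["Fp1", ] <- rec$samples["Fp1", ] + 0.6 * blink
  rec$samples["Fp2", ] <- rec$samples["Fp2", ] + 0.6 * blink
  rec$samples["EOGh", ] <- rec$samples["EOGh", ] + sacc
  rec$samples["F3", ] <- rec$samples["F3", ] + 0.5 * sacc
  rec$samples["F4", ] <- rec$samples["F4", ] - 0.5 * sacc
  res <- remove_eog(rec)
  expect_gte(length(res$removed_components), 2L)
  for (ch in c("Fp1", "F3"))
    expect_lt(max(abs(cor(res$recording$samples[ch, ], blink)),
                  abs(cor(res$recording$samples[ch, ], as.numeric(sacc)))), 0.1)
})

test_that("session and subject exclusion rules follow the protocol", {
  cfg <- rejection_config()
  mk_session <- function(subject, session, n, n_removed) {
    data.frame(subject = subject, session = session,
               trial = seq_len(n),
               removed = c(rep(TRUE, n_removed), rep(FALSE, n - n_removed)))
  }
  ## 15 of 160 remaining -> excluded; 16 of 160 remaining -> retained
  rep1 <- apply_exclusions(rbind(mk_session("A", 0, 160, 145),
                                 mk_session("A", 1, 160, 144)), cfg)
  expect_identical(rep1$sessions$excluded, c(TRUE, FALSE))
  expect_identical(rep1$sessions$n_out, c(15L, 16L))
  ## counts reconcile
  expect_equal(rep1$sessions$n_in,
               rep1$sessions$n_out + rep1$sessions$n_removed)

  ## the 10% rule dominates for large sessions: 17 of 200 remaining is
  ## below ceiling(0.1 * 200) = 20
  rep2 <- apply_exclusions(mk_session("B", 0, 200, 183), cfg)
  expect_true(rep2$sessions$excluded)

  ## subject exclusion: 9 of 17 sessions removed -> excluded; 8 of 17 -> kept
  mk_subject <- function(subject, n_bad, n_total = 17) {
    do.call(rbind, lapply(seq_len(n_total) - 1L, function(s)
      mk_session(subject, s, 20, if (s < n_bad) 20 else 0)))
  }
  rep3 <- apply_exclusions(rbind(mk_subject("C", 9), mk_subject("D", 8)), cfg)
  expect_identical(rep3$subjects$excluded[rep3$subjects$subject == "C"], TRUE)
  expect_identical(rep3$subjects$excluded[rep3$subjects$subject == "D"], FALSE)
})
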