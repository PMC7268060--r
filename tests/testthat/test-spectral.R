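sine_mat <- function(freq, amp, fs = 500, dur = 4, chans = "C3", phase = 0) {
  t_s <- (seq_len(dur * fs) - 1) / fs
  m <- matrix(rep(amp * sin(2 * pi * freq * t_s + phase), length(chans)),
              nrow = length(chans), byrow = TRUE)
  rownames(m) <- chans
  m
}

test_that("band power scales quadratically with amplitude and is band selective", {
  p1 <- band_power(sine_mat(10, 1), alpha_band(), 500)
  p2 <- band_power(sine_mat(10, 2), alpha_band(), 500)
  expect_equal(unname(p2 / p1), 4, tolerance = 1e-9)

  p20_alpha <- band_power(sine_mat(20, 1), alpha_band(), 500)
  p20_beta <- band_power(sine_mat(20, 1), beta_band(), 500)
  expect_gt(unname(p20_beta / (p20_alpha + 1e-12)), 1e3)

  expect_error(band_power(sine_mat(10, 1), band_definition("x", 200, 260), 500),
               "Nyquist")
  expect_error(band_definition("bad", 12, 8), "f_lo")
})

test_that("white noise has equal mean PSD in alpha and beta bands", {
  set.seed(41)
  x <- matrix(rnorm(500 * 60), nrow = 1, dimnames = list("C3", NULL))
  pa <- band_power(x, alpha_band(), 500)
  pb <- band_power(x, beta_band(), 500)
  ## flat-spectrum oracle: both estimate the same constant density
  expect_equal(unname(pa / pb), 1, tolerance = 0.15)
})

test_that("Welch variance shrinks with the number of windows", {
  set.seed(42)
  var_for_dur <- function(dur, reps = 60) {
    var(vapply(seq_len(reps), function(i)
      unname(band_power(matrix(rnorm(dur * 500), 1,
                               dimnames = list("C3", NULL)),
                        alpha_band(), 500)), 0))
  }
  v2 <- var_for_dur(2)
  v8 <- var_for_dur(8)
  ## 15 vs 3 windows: expect roughly 1/5 the variance; allow slack
  expect_lt(v8, v2 / 2)
})

test_that("ERD follows (M - R)/R x 100 exactly", {
  fs <- 500
  mk_ep <- function(rest_amp, move_amp) {
    trial <- list(trial = 1L,
                  rest = sine_mat(10, rest_amp, fs, 4, c("C3", "Cp3", "P3")),
                  prep = sine_mat(10, rest_amp, fs, 2, c("C3", "Cp3", "P3")),
                  move = sine_mat(10, move_amp, fs, 5, c("C3", "Cp3", "P3")))
    structure(list(trials = list(trial), fs = fs,
                   channel_labels = c("C3", "Cp3", "P3"),
                   channel_kinds = setNames(rep("EEG", 3), c("C3", "Cp3", "P3")),
                   subject_id = "S", session_index = 0L, lesion_side = "left",
                   dropped = data.frame()), class = "erd_epochs")
  }
  ch <- c("C3", "Cp3", "P3")
  ## M = 0.7 R  (amplitude ratio sqrt(0.7))  ->  -30%
  e <- compute_erd(mk_ep(1, sqrt(0.7)), alpha_band(), ch)
  expect_equal(e$erd_percent, -30, tolerance = 1e-9)
  ## M = R -> 0%
  expect_equal(compute_erd(mk_ep(1, 1), alpha_band(), ch)$erd_percent, 0,
               tolerance = 1e-9)
  ## M = 0 -> -100%
  expect_equal(compute_erd(mk_ep(1, 0), alpha_band(), ch)$erd_percent, -100,
               tolerance = 1e-9)
  ## R = 0 -> trial skipped, and with a single trial that is an error
  expect_error(suppressWarnings(compute_erd(mk_ep(0, 1), alpha_band(), ch)),
               "positive reference power")
  expect_error(compute_erd(mk_ep(1, 1), alpha_band(), c("C3", "Nope")), "Nope")
})

test_that("session ERD is invariant under global amplitude scaling", {
  set.seed(43)
  spec <- tiny_spec()
  ses <- simulate_session(spec, -40, n_trials = 4)
  ep <- session_to_epochs(ses)
  hemi <- map_hemispheres("left")
  e1 <- compute_erd(ep, alpha_band(), hemi$ipsilesional)
  ses2 <- ses
  ses2$trials <- lapply(ses$trials, function(tr) {
    tr$iti <- tr$iti * 3.7; tr$prep <- tr$prep * 3.7; tr$move <- tr$move * 3.7
    tr
  })
  e2 <- compute_erd(session_to_epochs(ses2), alpha_band(), hemi$ipsilesional)
  expect_equal(e2$erd_percent, e1$erd_percent, tolerance = 1e-9)
})

test_that("trialwise and pooled averaging agree for homogeneous trials", {
  set.seed(44)
  ses <- simulate_session(tiny_spec(), -50, n_trials = 6, noise = FALSE)
  ep <- session_to_epochs(ses)
  hemi <- map_hemispheres("left")
  et <- compute_erd(ep, alpha_band(), hemi$ipsilesional, method = "trialwise")
  ep2 <- session_to_epochs(ses)
  ep2$trials <- ep$trials
  epool <- compute_erd(ep2, alpha_band(), hemi$ipsilesional, method = "pooled")
  expect_equal(et$erd_percent, -50, tolerance = 0.5)
  expect_equal(epool$erd_percent, et$erd_percent, tolerance = 1)
})

test_that("hemisphere mapping is correct and involutive", {
  expect_identical(map_hemispheres("left")$ipsilesional, c("C3", "Cp3", "P3"))
  expect_identical(map_hemispheres("right")$ipsilesional, c("C4", "Cp4", "P4"))
  expect_identical(map_hemispheres("left")$contralesional,
                   map_hemispheres("right")$ipsilesional)
  expect_error(map_hemispheres("bilateral"), "unknown")
})

test_that("SMR calibration separates conditions and stays flat under the null", {
  set.seed(45)
  spec <- tiny_spec()
  mk_seg <- function(target) {
    tr <- simulate_trial(spec, target, smr_freq = 10)
    tr$move[, 1:1500]
  }
  rest <- lapply(1:12, function(i) mk_seg(0))       # no suppression: "rest-like"
  move <- lapply(1:12, function(i) mk_seg(-85))
  cal <- calibrate_smr(rest, move, fs = spec$fs)
  expect_true(cal$selected_band[1] <= 10 && cal$selected_band[2] >= 10)
  expect_gt(max(cal$bins$r2), 0.8)
  expect_true(all(cal$bins$r2 >= 0 & cal$bins$r2 <= 1))
  expect_true(all(cal$selected_electrodes %in%
                  c("C3", "Cp3", "P3", "C4", "Cp4", "P4")))

  ## identical distributions: no bin strongly preferred
  null_a <- lapply(1:12, function(i) mk_seg(-30))
  null_b <- lapply(1:12, function(i) mk_seg(-30))
  cal0 <- calibrate_smr(null_a, null_b, fs = spec$fs)
  expect_lt(max(cal0$bins$r2), 0.4)

  expect_error(calibrate_smr(rest[1:3], move, fs = spec$fs), "10 segments")
  expect_error(calibrate_smr(rest, move, fs = spec$fs, scan_range = c(5, 300)),
               "Nyquist")
})

test_that("cohort-mean selected SMR frequency falls in the alpha band", {
  set.seed(46)
  spec <- tiny_spec()
  freqs <- rnorm(4, spec$smr_freq_mean, spec$smr_freq_sd)
  freqs <- pmin(pmax(freqs, 8.5), 11.5)        # generator's truncation
  peaks <- vapply(freqs, function(f0) {
    rest <- lapply(1:10, function(i)
      simulate_trial(spec, 0, smr_freq = f0)$move[, 1:1250])
    move <- lapply(1:10, function(i)
      simulate_trial(spec, -80, smr_freq = f0)$move[, 1:1250])
    calibrate_smr(rest, move, fs = spec$fs)$peak_freq
  }, 0)
  expect_gte(mean(peaks), 8)
  expect_lte(mean(peaks), 12)
})
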