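## Shared fixtures and independent oracle implementations.
## Oracles deliberately avoid the package's own code paths: plain loops and
## base R only.

tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(n_subjects = 4, sessions_per_subject = 4, trials_per_session = 8,
         session_jitter_sd = 0, trial_jitter_sd = 0),
    list(...))
  do.call(cohort_spec, args)
}

## Independent band-pass (frequency-domain, written separately from the
## package's fft_bandpass: explicit two-sided mask built from fftfreq logic)
oracle_bandpass <- function(x, fs, lo, hi) {
  n <- length(x)
  k <- 0:(n - 1)
  freq <- ifelse(k <= n / 2, k, k - n) * fs / n
  keep <- abs(freq) >= lo & abs(freq) <= hi
  Re(fft(fft(x) * keep, inverse = TRUE) / n)
}

## Independent combined-z trial statistic (loop form) given precomputed
## per-channel session means/sds
oracle_trial_zstat <- function(xf, mu, sd_) {
  nch <- nrow(xf)
  best <- -Inf
  for (t in seq_len(ncol(xf))) {
    s <- 0
    for (c in seq_len(nch)) s <- s + (xf[c, t] - mu[c]) / sd_[c]
    best <- max(best, abs(s))
  }
  best / sqrt(nch)
}

## Independent waveform length of one window
oracle_wl <- function(x) {
  acc <- 0
  for (i in seq_len(length(x) - 1)) acc <- acc + abs(x[i + 1] - x[i])
  acc
}

## Per-subject OLS trajectory fits (oracle for stage-1 conditional modes)
oracle_ols_trajectories <- function(erd) {
  subs <- unique(erd$subject)
  out <- data.frame(subject = subs, intercept = NA_real_, slope = NA_real_)
  for (i in seq_along(subs)) {
    d <- erd[erd$subject == subs[i], ]
    co <- coef(lm(erd_percent ~ session, data = d))
    out$intercept[i] <- co[1]
    out$slope[i] <- co[2]
  }
  out
}

## 99% binomial bounds on a count
binom99 <- function(n, p) qbinom(c(0.005, 0.995), n, p)

expect_flag_subset <- function(flags_hi, flags_lo) {
  expect_true(all(which(flags_hi) %in% which(flags_lo)))
}
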