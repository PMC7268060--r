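#' @keywords internal
"_PACKAGE"

## Channel montage used throughout: 16 scalp EEG positions, two EOG
## derivations and four bipolar EMG channels per arm.
EEG_CHANNELS <- c("Fp1", "Fp2", "F3", "Fz", "F4", "T7", "C3", "Cz", "C4",
                  "T8", "Cp3", "Cp4", "P3", "Pz", "P4", "Oz")
EOG_CHANNELS <- c("EOGv", "EOGh")
EMG_MUSCLES  <- c("ECU", "ED", "BIC", "TRI")
EMG_CHANNELS <- c(paste0("EMG_", EMG_MUSCLES, "_L"),
                  paste0("EMG_", EMG_MUSCLES, "_R"))
ALL_CHANNELS <- c(EEG_CHANNELS, EOG_CHANNELS, EMG_CHANNELS)
ALL_KINDS <- c(rep("EEG", length(EEG_CHANNELS)),
               rep("EOG", length(EOG_CHANNELS)),
               rep("EMG", length(EMG_CHANNELS)))
names(ALL_KINDS) <- ALL_CHANNELS

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Infer channel kinds (EEG/EOG/EMG) from channel labels
#' @noRd
infer_channel_kinds <- function(labels) {
  kind <- ifelse(grepl("^EOG", labels), "EOG",
          ifelse(grepl("^EMG", labels), "EMG", "EEG"))
  names(kind) <- labels
  kind
}

#' Side (left/right) of an EMG channel from its label suffix
#' @noRd
emg_channel_side <- function(labels) {
  side <- ifelse(grepl("_L$", labels), "left",
          ifelse(grepl("_R$", labels), "right", NA_character_))
  names(side) <- labels
  side
}

#' Brick-wall FFT band-pass filter
#'
#' Zero-phase band-pass by zeroing Fourier coefficients outside
#' `[f_lo, f_hi]`. Adequate for the artifact detectors, which threshold a
#' z-scored statistic and do not depend on an exact transition band.
#'
#' @param x numeric vector (one channel).
#' @param fs sampling rate in Hz.
#' @param f_lo,f_hi band edges in Hz (inclusive).
#' @return filtered numeric vector of the same length.
#' @keywords internal
fft_bandpass <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  if (n == 0L) stopf("empty signal")
  if (f_hi > fs / 2) stopf("band edge %g Hz above Nyquist (%g Hz)", f_hi, fs / 2)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)  # mirrored frequencies of the two-sided spectrum
  X[f < f_lo | f > f_hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Pink (1/f) noise by spectral synthesis
#'
#' Gaussian white spectrum shaped by 1/sqrt(f), inverse transformed and
#' standardized to unit standard deviation before scaling.
#'
#' @param n number of samples.
#' @param amplitude target standard deviation (microvolts).
#' @return numeric vector of length `n`.
#' @keywords internal
pink_noise <- function(n, amplitude = 1) {
  if (n < 2L) return(stats::rnorm(n, sd = amplitude))
  nf <- n %/% 2L
  mag <- 1 / sqrt(seq_len(nf))
  re <- stats::rnorm(nf) * mag
  im <- stats::rnorm(nf) * mag
  spec <- complex(real = c(0, re), imaginary = c(0, im))
  full <- c(spec, Conj(rev(spec[2:(nf + 1L)])))[seq_len(n)]
  x <- Re(stats::fft(full, inverse = TRUE))
  s <- stats::sd(x)
  if (s == 0) return(rep(0, n))
  x / s * amplitude
}

#' Correlation that returns 0 instead of NA for zero-variance inputs
#' @noRd
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}
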