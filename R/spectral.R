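#' Frequency band definition
#'
#' @param name band name.
#' @param f_lo,f_hi band edges in Hz, inclusive on both sides (12 Hz belongs
#'   to both the alpha and the beta band under the conventional overlapping
#'   definitions).
#' @return object of class `band_definition`.
#' @export
band_definition <- function(name, f_lo, f_hi) {
  if (!(f_lo > 0 && f_lo < f_hi)) stopf("need 0 < f_lo < f_hi")
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi),
            class = "band_definition")
}

#' @rdname band_definition
#' @export
alpha_band <- function() band_definition("alpha", 8, 12)

#' @rdname band_definition
#' @export
beta_band <- function() band_definition("beta", 12, 25)

#' Welch power spectral density
#'
#' Mean periodogram over Hann-windowed segments with 50% overlap; segments
#' are demeaned before windowing, and the one-sided density is normalized so
#' that the integral over frequency equals the signal variance.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param window_s segment length in seconds (1 s gives 1 Hz resolution).
#' @param overlap fractional segment overlap.
#' @return list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, window_s = 1, overlap = 0.5) {
  nw <- round(window_s * fs)
  if (length(x) < nw) stopf("segment shorter than one Welch window")
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, length(x) - nw + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nw) - 1) / nw))   # periodic Hann
  U <- sum(w^2)
  n_half <- nw %/% 2L
  acc <- numeric(n_half + 1L)
  for (s in starts) {
    seg <- x[s:(s + nw - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / (fs * U)
    ps <- p[seq_len(n_half + 1L)]
    ps[2:(n_half + if (nw %% 2L == 0L) 0L else 1L)] <-
      2 * ps[2:(n_half + if (nw %% 2L == 0L) 0L else 1L)]
    acc <- acc + ps
  }
  list(freq = (0:n_half) * fs / nw, psd = acc / length(starts))
}

#' Mean band power per channel
#'
#' Welch PSD per channel, averaged over the frequency bins inside the band
#' (edges inclusive).
#'
#' @param segment channels x samples matrix (or a vector for one channel).
#' @param band a [band_definition()] or numeric pair `(f_lo, f_hi)`.
#' @param fs sampling rate in Hz.
#' @param window_s Welch window length in seconds.
#' @return named numeric vector of mean PSD per channel.
#' @export
band_power <- function(segment, band, fs, window_s = 1) {
  if (is.numeric(band) && length(band) == 2L)
    band <- band_definition("custom", band[1], band[2])
  if (band$f_hi >= fs / 2) stopf("band extends beyond the Nyquist frequency")
  if (is.null(dim(segment))) segment <- matrix(segment, nrow = 1)
  vapply(seq_len(nrow(segment)), function(ch) {
    ps <- welch_psd(segment[ch, ], fs, window_s = window_s)
    sel <- ps$freq >= band$f_lo & ps$freq <= band$f_hi
    mean(ps$psd[sel])
  }, 0) |> stats::setNames(rownames(segment))
}

#' Map lesion side to ipsi-/contralesional motor channel sets
#'
#' The three motor channels over each hemisphere are C3/Cp3/P3 (left) and
#' C4/Cp4/P4 (right); the ipsilesional set is on the lesion side.
#'
#' @param lesion_side `"left"` or `"right"`.
#' @return list with `ipsilesional` and `contralesional` channel vectors.
#' @export
map_hemispheres <- function(lesion_side) {
  if (!lesion_side %in% c("left", "right"))
    stopf("unknown lesion side: %s", lesion_side)
  if (lesion_side == "left")
    list(ipsilesional = MOTOR_LEFT, contralesional = MOTOR_RIGHT)
  else
    list(ipsilesional = MOTOR_RIGHT, contralesional = MOTOR_LEFT)
}

#' Event-related desynchronization of one session
#'
#' For every artifact-free trial the movement-phase band power `M` and the
#' rest (reference) band power `R` are computed per channel, averaged over
#' the three hemisphere channels, and combined as
#' `ERD = (M - R) / R * 100` (percent; negative = desynchronization).
#' The session value is the mean of the per-trial ERDs (`method =
#' "trialwise"`, the default) or the ERD of the trial-averaged powers
#' (`method = "pooled"`, the classical alternative).
#'
#' @param epochs an `erd_epochs` object (cleaned: pass only surviving
#'   trials, e.g. via `subset_epochs()`).
#' @param band a [band_definition()].
#' @param channels hemisphere channel set (e.g. from [map_hemispheres()]).
#' @param hemisphere label stored in the result (`"ipsilesional"` /
#'   `"contralesional"`).
#' @param method `"trialwise"` or `"pooled"`.
#' @return data frame (one row) with `subject`, `session_index`,
#'   `hemisphere`, `band`, `erd_percent`, `n_trials_used`; per-trial values
#'   in attribute `per_trial`.
#' @export
compute_erd <- function(epochs, band = alpha_band(),
                        channels, hemisphere = NA_character_,
                        method = c("trialwise", "pooled")) {
  stopifnot(inherits(epochs, "erd_epochs"))
  method <- match.arg(method)
  if (!length(epochs$trials)) stopf("no artifact-free trials to analyse")
  miss <- setdiff(channels, epochs$channel_labels)
  if (length(miss)) stopf("channels not in recording: %s", paste(miss, collapse = ", "))
  fs <- epochs$fs
  mr <- t(vapply(epochs$trials, function(tr) {
    c(M = mean(band_power(tr$move[channels, , drop = FALSE], band, fs)),
      R = mean(band_power(tr$rest[channels, , drop = FALSE], band, fs)))
  }, c(M = 0, R = 0)))
  ok <- mr[, "R"] > 0
  if (!all(ok)) warnf("%d trial(s) with zero reference power skipped", sum(!ok))
  if (!any(ok)) stopf("no trial with positive reference power")
  per_trial <- (mr[ok, "M"] - mr[ok, "R"]) / mr[ok, "R"] * 100
  erd <- if (method == "trialwise") mean(per_trial)
         else (mean(mr[ok, "M"]) - mean(mr[ok, "R"])) / mean(mr[ok, "R"]) * 100
  out <- data.frame(subject = epochs$subject_id,
                    session_index = epochs$session_index,
                    hemisphere = hemisphere, band = band$name,
                    erd_percent = erd, n_trials_used = sum(ok))
  attr(out, "per_trial") <- per_trial
  out
}

#' Keep a subset of trials of an epochs object
#'
#' @param epochs an `erd_epochs` object.
#' @param keep logical or integer index over current trials.
#' @return the filtered `erd_epochs`.
#' @export
subset_epochs <- function(epochs, keep) {
  epochs$trials <- epochs$trials[keep]
  epochs
}

#' ERD samples for both hemispheres and several bands
#'
#' @param epochs a cleaned `erd_epochs` object with known `lesion_side`.
#' @param bands list of [band_definition()]s.
#' @param method passed to [compute_erd()].
#' @return tidy data frame of ERD samples (rows: hemisphere x band).
#' @export
erd_samples <- function(epochs, bands = list(alpha_band()),
                        method = "trialwise") {
  hemi <- map_hemispheres(epochs$lesion_side)
  out <- list()
  for (b in bands)
    for (h in names(hemi))
      out[[length(out) + 1L]] <-
        compute_erd(epochs, b, hemi[[h]], hemisphere = h, method = method)
  do.call(rbind, out)
}

#' Individual sensorimotor-rhythm calibration
#'
#' Scans 2 Hz bins across the requested range and measures, per bin, how
#' well log band power separates rest from movement segments: the squared
#' point-biserial correlation between condition label and log band power
#' (pooled over the central-parietal channels). The selected band is the
#' contiguous run of bins around the maximum whose discriminability stays
#' above half the maximum; electrodes are ranked by their per-channel
#' discriminability within the selected band.
#'
#' @param rest_segments,move_segments lists of channels x samples matrices.
#' @param fs sampling rate in Hz.
#' @param scan_range numeric pair (Hz) delimiting the scan.
#' @param channels channels used (default: the six central-parietal motor
#'   channels present in the data).
#' @param bin_hz scan bin width (Hz).
#' @return object of class `smr_calibration`: data frame `bins`
#'   (`f_lo`, `f_hi`, `r2`), `selected_band` (Hz pair),
#'   `selected_electrodes` (ranked), `peak_freq` (bin center of the
#'   maximum).
#' @export
calibrate_smr <- function(rest_segments, move_segments, fs,
                          scan_range = c(5, 30), channels = NULL,
                          bin_hz = 2) {
  if (length(rest_segments) < 10L || length(move_segments) < 10L)
    stopf("need at least 10 segments per condition")
  if (scan_range[2] >= fs / 2) stopf("scan range beyond Nyquist")
  first <- rest_segments[[1]]
  channels <- channels %||% intersect(c(MOTOR_LEFT, MOTOR_RIGHT), rownames(first))
  if (!length(channels)) stopf("no central-parietal channels found")
  edges <- seq(scan_range[1], scan_range[2], by = bin_hz)
  if (edges[length(edges)] < scan_range[2]) edges <- c(edges, scan_range[2])
  n_bins <- length(edges) - 1L

  logpow <- function(seg, lo, hi)
    log(band_power(seg[channels, , drop = FALSE], c(lo, hi), fs))
  labels <- c(rep(0, length(rest_segments)), rep(1, length(move_segments)))
  segs <- c(rest_segments, move_segments)

  r2 <- numeric(n_bins)
  r2_chan <- matrix(0, n_bins, length(channels),
                    dimnames = list(NULL, channels))
  for (b in seq_len(n_bins)) {
    lp <- t(vapply(segs, logpow, numeric(length(channels)),
                   lo = edges[b], hi = edges[b + 1L]))
    pooled <- rowMeans(lp)
    r2[b] <- safe_cor(pooled, labels)^2
    r2_chan[b, ] <- vapply(seq_along(channels),
                           function(j) safe_cor(lp[, j], labels)^2, 0)
  }

  peak <- which.max(r2)
  lo <- peak; hi <- peak
  while (lo > 1L && r2[lo - 1L] >= r2[peak] / 2) lo <- lo - 1L
  while (hi < n_bins && r2[hi + 1L] >= r2[peak] / 2) hi <- hi + 1L
  sel_band <- c(edges[lo], edges[hi + 1L])
  in_sel <- lo:hi
  elec_score <- colMeans(r2_chan[in_sel, , drop = FALSE])
  structure(list(
    bins = data.frame(f_lo = edges[-length(edges)], f_hi = edges[-1], r2 = r2),
    selected_band = sel_band,
    selected_electrodes = names(sort(elec_score, decreasing = TRUE)),
    electrode_r2 = sort(elec_score, decreasing = TRUE),
    ## discriminability-weighted center of the selected band: robust to the
    ## rhythm straddling a bin edge
    peak_freq = {
      ctr <- (edges[in_sel] + edges[in_sel + 1L]) / 2
      if (sum(r2[in_sel]) > 0) sum(ctr * r2[in_sel]) / sum(r2[in_sel])
      else mean(ctr)
    }),
    class = "smr_calibration")
}

#' @export
print.smr_calibration <- function(x, ...) {
  cat(sprintf("<smr_calibration> peak %g Hz, selected band %g-%g Hz, max r2 = %.3f\n",
              x$peak_freq, x$selected_band[1], x$selected_band[2], max(x$bins$r2)))
  invisible(x)
}

#' Write ERD samples as tidy TSV
#'
#' @param erd data frame of ERD samples.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_erd_samples <- function(erd, path) {
  utils::write.table(erd, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
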