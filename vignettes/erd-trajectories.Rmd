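---
title: "Modeling longitudinal EEG desynchronization as a biomarker of motor recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling longitudinal EEG desynchronization as a biomarker of motor recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erdtraj)
```

## The scientific problem

Severely paralyzed chronic stroke patients can train upper-limb movement
with a brain-machine interface (BMI): attempted movement suppresses the
sensorimotor rhythm (SMR), an alpha-range (8--12 Hz) oscillation over
central-parietal cortex, and that suppression drives a robotic orthosis.
The question this package addresses is whether the *longitudinal evolution*
of that suppression over weeks of training carries prognostic information
about clinical improvement.

The quantity of interest is event-related desynchronization,

$$\mathrm{ERD} = \frac{M - R}{R} \times 100\,\%$$

where $M$ is the mean alpha band power during the movement-attempt phase of
a trial and $R$ the band power in a reference window (the last 4 s of the
inter-trial interval). More negative ERD means stronger desynchronization.
Band powers are Welch estimates averaged over the three motor channels of a
hemisphere (C3/Cp3/P3 or C4/Cp4/P4), with no other spatial filtering.

## The two-stage model

**Stage 1.** Session-mean ERD values of all subjects are modeled jointly by
a linear mixed-effects model,

$$\mathrm{ERD}_{ij} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i})\, j + \varepsilon_{ij},$$

with 0-based session index $j$ (so the intercept is the *initial* ERD),
correlated random intercepts and slopes per subject, and REML estimation by
default. Per-subject coefficients are fixed effects plus conditional modes
(BLUPs). When the correlated random-effects fit is singular the model is
automatically refit with independent random effects and the downgrade is
recorded. Session indices are *not* renumbered after session exclusion, so
true temporal spacing is preserved; the mixed model tolerates unequal and
unequally spaced sessions.

**Stage 2.** Clinical change is the post-intervention combined upper-limb
Fugl-Meyer score (cFMA, 0--54) minus the mean of two baseline assessments.
It is regressed on the subject-level coefficients with an interaction:

$$\Delta \mathrm{cFMA}_i = \gamma_0 + \gamma_1 I_i + \gamma_2 S_i + \gamma_3 I_i S_i + \eta_i .$$

Predictors are used raw (uncentered) because the initial ERD is interpreted
on its raw scale through a median split into "strong" (below the median,
i.e. more negative) and "weak" subgroups; within the subgroups, simple
regressions of $\Delta$cFMA on the *contralesional* slope mirror the
interaction. The progressive laterality coefficient
$\mathrm{pLC} = S_H - S_L$ (healthy-hemisphere slope minus lesioned-
hemisphere slope) summarizes interhemispheric rebalancing: positive values
mean progressively stronger ipsilesional desynchronization, and pLC is
antisymmetric under hemisphere swap and invariant to adding a constant to
both slopes.

Degrees of freedom are structural throughout: the interaction model has
$F(3, n-4)$, simple regressions $F(1, n-2)$, even if a predictor happens to
be aliased in a degenerate sample (the coefficient is then `NA` but the
declared model is unchanged). No multiple-testing correction is applied,
matching the original reporting; treat the subgroup p-values accordingly.

## Artifact rejection cascade

The fully automated cascade mirrors the acquisition protocol's offline
cleaning:

1. **Ocular artifacts**: one seeded FastICA decomposition of the EEG
   channels per session; components whose absolute Pearson correlation with
   any EOG channel exceeds 0.7 (configurable) are zeroed and the EEG
   reconstructed. EOG channels are never modified.
2. **Cranial EMG**: EEG band-passed 110--140 Hz, z-scored per channel
   against that session's per-channel statistics, combined across channels
   as $\sum_c z_c / \sqrt{N}$, and a trial is flagged when the absolute
   combined statistic *strictly* exceeds 4 anywhere in the trial. The
   $\sqrt{N}$ normalization (the convention of the established artifact
   toolboxes) keeps the statistic at unit variance for independent channels
   while coherent artifacts on $k$ channels grow as $\sqrt{k}\,z$; plain
   averaging would make a 10-SD burst on 3 of 16 channels invisible.
   The absolute value matters for the offset detector, where jumps go
   either way.
3. **Offset artifacts**: the same statistic on the broadband signal with
   threshold 20.
4. **Muscle contractions**: waveform length (sum of absolute successive
   differences) of each EMG channel in non-overlapping 250 ms windows; a
   contraction is a window exceeding the channel's session mean by 3
   session SDs. A trial is removed when a *paretic-side* contraction
   overlaps the rest window or a *healthy-side* contraction overlaps the
   movement phase -- the two compensation patterns; paretic-side activity
   during the movement attempt is the trained behavior and is allowed.

Sessions keeping fewer than `max(16, ceiling(0.10 * n_trials))` trials are
excluded; a subject is excluded when at least `ceiling(n_sessions / 2)`
sessions were removed (the protocol states "half"; the ceiling resolves odd
counts).

Design notes on open points: z-score statistics are computed over the
concatenated trials of one session per channel (the normalization window is
otherwise unspecified; per-session statistics adapt to montage drift);
signed samples (not rectified) enter the z-scores; "3 SDs of the data" for
the waveform length is read as 3 SDs of the session's *waveform-length
distribution* -- SDs of raw samples would be dimensionally inconsistent
with a quantity summed over a window.

An important property of the max-over-samples detectors: with an 11 s trial
the null distribution of the maximum combined z sits close to 4, so even
artifact-free Gaussian trials are flagged at a substantial rate. This is
intrinsic to the published procedure, not a bug; the test suite therefore
validates the false-flag rate against a Monte-Carlo null oracle rather than
against zero. Real EEG has heavier tails and higher in-band background, so
empirical rejection rates on real data are not comparable to the synthetic
null rate.

## The synthetic cohort: what it emulates, and what not

`cohort_spec()` / `simulate_cohort()` generate cohorts with known ground
truth. Defaults encode the emulated training protocol: 22 analyzed
subjects, 17 ± 1.8 sessions of 165 ± 19.5 trials; trials are an inter-trial
interval of 4--7 s, 2 s preparation, 5 s movement at 500 Hz over 16 EEG + 2
EOG + 8 EMG channels; baseline cFMA 12.22 ± 8.82. Population trajectory
defaults ($\beta_0 = -30$ %, near the reported initial-ERD median;
$\beta_1 = -0.5$ %/session; random-effect SDs 10 and 0.4; residual 8 %) and
the outcome coefficients $\gamma = (2, 0.05, -4, -0.15)$ with residual SD 3
cFMA points define the stated world of the recovery tests; where the
protocol gives no value, these were chosen once as clinically plausible
magnitudes (improvements of a few Fugl-Meyer points, driven mainly by the
slope and its interaction with the initial ERD) and are not tuned
thereafter.

Signals are built physically: a sinusoidal SMR at the subject's individual
frequency (10.6 ± 1 Hz, truncated to 8.5--11.5 Hz) on the motor channels
with gains 1/0.85/0.7 across C/Cp/P rows, on top of 1/f background plus
white measurement noise (the protocol says nothing about the spectrum
outside the bands of interest). The movement-phase amplitude is scaled by
$\sqrt{1 + \mathrm{ERD}/100}$, so ERD noise enters through the amplitude --
generated signals are always physical, and session ERD targets are clamped
at $-100$ %. Artifacts are injected per trial as independent Bernoulli
draws (defaults: blinks 0.05, high-frequency bursts 0.02, offsets 0.01, EMG
bursts 0.05 -- the protocol reports no rates; these give the few-percent
contamination typical of cooperative clinical recordings), always inside
the analyzed span of the trial, and every injection is logged as ground
truth.

Two signal levels exist deliberately. `signal = "erd"` emits session-level
ERD values straight from the trajectory model -- the scale the statistics
operate on, cheap enough for hundreds of replicate cohorts.
`signal = "raw"` synthesizes every trial's multichannel signal and is meant
for small configurations exercising the full chain. Trials within a
session are exchangeable (no fatigue trend -- the protocol states none),
the preparation phase carries resting alpha, no volume-conduction head
model is simulated, and beta-band dynamics are not planted. A green test on
this world therefore establishes correctness of the *pipeline*, not
realism of scalp EEG; parameter-recovery results transfer only insofar as
the linear-trajectory generative model holds.

## Numerical choices

* Welch PSD: 1 s periodic Hann windows, 50 % overlap, segments demeaned;
  1 Hz resolution is adequate for a 4 Hz-wide band. Band edges are
  inclusive on both sides (12 Hz belongs to alpha and beta, as the
  overlapping printed definitions imply).
* Per-trial ERD values are averaged across trials ("trialwise", the
  default reading of "mean ERD over all trials"); the classical
  average-powers-then-ratio alternative is available as
  `method = "pooled"` and agrees for homogeneous trials.
* Trials with zero reference power are skipped with a warning; a session
  ERD of exactly $-100$ % occurs iff movement band power vanishes in all
  trials.
* SMR calibration uses the squared point-biserial correlation between
  condition and *log* band power (variance stabilization; unspecified in
  the protocol) per 2 Hz bin, selects the contiguous bins above half the
  maximum, and reports a discriminability-weighted center frequency.
* PSD is computed per channel and powers averaged afterwards (the order is
  unspecified in the protocol; per-channel-then-average matches the "no
  other spatial filters" statement).
* Epochs are half-open sample intervals `[start, end)` with 0-based event
  onsets; concatenating rest/preparation/movement reproduces the
  continuous span sample-exactly. External trials with an inter-trial
  interval under 4 s are dropped, never shortened: the reference duration
  is fixed by the protocol.
* Median split: below-median initial ERD is the "strong" group (more
  negative = stronger); even cohorts split exactly in half, ties straddling
  the median are resolved by stable (key, subject) order; with an odd count
  the median subject goes to the "weak" side.
* Likelihood-ratio comparisons refit by full ML when fixed effects differ
  (REML likelihoods are not comparable across fixed-effects structures);
  the random-slope-vs-intercept-only comparison has 2 df (slope variance +
  correlation). The boundary-of-parameter-space conservatism of that
  test is accepted, as in the original analysis.
* FastICA is implemented in-package (symmetric, tanh contrast, seeded
  orthonormal initialization, PCA whitening) because no ICA package is
  available in the target environment; determinism of the artifact cascade
  follows from the fixed seed.

## Planted-effect tests: a design-time power analysis

The acceptance checks require that a *planted* stage-2 interaction sign be
recovered in at least 95 % of replicate cohorts, and that the full sign
pattern of $\gamma$ be recovered in at least 90 %. Neither the protocol nor
the acceptance criteria fix the noise level of the "strong signal" world,
so it was fixed a priori by a power analysis over candidate noise levels
(200 replicates each, n = 22, 17 sessions, $\gamma$ as above):

| $\sigma_\varepsilon$ (ERD %) | $\sigma_{out}$ (cFMA) | all-sign rate | $\gamma_3$-sign rate |
|---|---|---|---|
| 8 | 3 (defaults) | -- | 0.69 |
| 4 | 1 | 0.76 | 0.96 |
| 2 | 0.5 | 0.95 | 1.00 |
| 1 | 0.25 | 1.00 | 1.00 |

$\sigma_\varepsilon = 1$, $\sigma_{out} = 0.25$ was frozen as the planted
regime: effects dominate noise, so the checks probe *identifiability* of
the two-stage estimator. At the realistic default noise, recovering the
sign of the tiny $\gamma_1$ main effect (0.05 points per ERD percent) is
not expected -- which is precisely why the source analysis is reported at
n = 22 with modest fits. The type-I check (nominal 5 % rejection of the
stage-2 F test under independent outcomes) holds exactly conditional on
the predictors and is run with directly drawn trajectories.

## Known limitations

* The BMI control loop, orthosis feedback contingency and lesion imaging
  are out of scope; the pipeline starts at recorded signals.
* EDF support covers plain 16-bit EDF with sidecar TSV events, not EDF+
  embedded annotations; BrainVision support covers binary multiplexed
  float32/int16.
* The synthetic SMR is sinusoidal; spectral-shape statistics (bandwidth,
  harmonics, 1/f slope fits) should not be validated against this
  generator.
* Stage-2 inference at n = 22 with uncentered interactions is fragile when
  the stage-1 slope variance collapses; the package then reports an `NA`
  interaction coefficient with structural dfs and warns about the
  ill-conditioned design rather than silently dropping the term.
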