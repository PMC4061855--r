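---
title: "Wavelet power and inter-site phase locking for oddball EEG: methods and design"
author: "wavepls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet power and inter-site phase locking for oddball EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavepls)
```

# The scientific problem

Listeners differ in how their cortex responds to speech sounds that are
linguistically relevant in some languages but not others — lexical tones
being the classic case — and short laboratory training can change those
responses.  Two complementary measures of the oscillatory EEG are commonly
used to track such changes in an auditory oddball paradigm (frequent
*standard* syllables interspersed with rare *deviants*):

* **time-varying spectral power** in the alpha (8–13 Hz) and gamma
  (28–50 Hz) ranges, estimated per trial by complex Morlet wavelet
  convolution, averaged into an *evolutionary spectrum* per electrode and
  condition, and baseline-corrected against the pre-stimulus interval; and
* the **phase-locking statistic (PLS)**, the modulus of the trial-averaged
  unit phasor of the phase *difference* between each electrode and a
  reference electrode, which quantifies how stable the relative phase of
  two sites is across trials (0 = random, 1 = perfectly locked),
  independent of amplitude.

`wavepls` implements this analysis chain end to end — epoched-EEG
containers and IO, mastoid re-referencing, artifact screening, the wavelet
family, power and PLS, band/time-window region-of-interest (ROI)
extraction over a 39-channel montage, and mixed repeated-measures ANOVA
with Greenhouse–Geisser (GG) correction — together with a synthetic
oddball-EEG generator whose oscillatory content and phase coupling are
known exactly, so that every stage can be validated against ground truth
or closed-form theory.

# The wavelet family

Kernels are generated in the time domain for analysis frequencies
$f_0 = 8, 9, \dots, 80$ Hz:

$$ g(t) = A' \, e^{-t^2 / (2\sigma_t^2)} \, e^{i 2 \pi f_0 t}, $$

with a constant ratio $m = f_0/\sigma_f = 9$ between each kernel's centre
frequency and its spectral width, and $A'$ fixed numerically so that every
sampled kernel has unit energy ($\sum |g|^2 \Delta t = 1$).

**Width convention.**  Two conventions for "spectral width" coexist in the
wavelet literature: the standard deviation of the Gaussian *amplitude*
spectrum, and that of the *energy* (squared-amplitude) spectrum, which is
smaller by $\sqrt{2}$.  `wavepls` defines $\sigma_f$ on the **energy
spectrum** — the quantity one actually measures from a kernel's
periodogram — so the envelope width is
$\sigma_t = 1/(2\sqrt{2}\,\pi\sigma_f)$.  With this convention the
FFT-measured second-moment width of every kernel satisfies
$f_0/\hat\sigma_f = 9$ to well within 2 %, which is the package's
acceptance check on the family.  At $f_0 = 45$ Hz, $\sigma_f = 5$ Hz.

**Support and edges.**  Kernels are truncated at $\pm 4 \sigma_t$ (energy
loss far below $10^{-6}$) and forced to odd length.  At $f_0 = 8$ Hz the
support (519 samples at 512 Hz) slightly exceeds a one-second epoch; the
zero-padded FFT convolution handles this exactly, so the transform refuses
an epoch only when a kernel's $\pm 2\sigma_t$ core covers *every* sample —
in that case no estimate in the epoch is usable and the error message
suggests longer epochs or a higher `f_min`.  Estimates within $2\sigma_t$
of an epoch edge are flagged in an `edge_mask` but never silently dropped;
with one-second epochs the gamma window (200–400 ms) is fully unmasked and
only the lowest alpha frequencies carry flags inside the alpha window.

**Normalization trade-off.**  Unit-energy kernels make the total
time-frequency energy of a unit-energy input comparable across $f_0$, but
they weight the kernel spectrum by $1/f_0$; a pure sinusoid's measured
power peak therefore sits exactly on the true grid frequency through the
alpha band and the centre of gamma (verified to 41 Hz) but may fall one
1-Hz grid step low above roughly 45 Hz.  This is an intrinsic property of
the equal-energy convention, not an implementation artifact; band *means*
over 6–23 bins are insensitive to it.

Each trial is multiplied by a cosine-square taper before convolution
(`taper_fraction = 0.1` per edge by default; 0.5 reproduces the Hann
window).  The taper suppresses the epoch-edge discontinuity without
touching the analysis windows, which start 100 ms after onset.

# Power, baseline, and PLS

Single-trial power is the squared modulus of the convolution; trial
averaging gives the evolutionary spectrum.  The mean over the baseline
interval (280 to 100 ms *before* onset, half-open `[-280, -100)`) is
subtracted per channel and frequency — subtraction only, no division or dB
scaling, and the baseline is computed per condition cell.  Baseline
correction and trial averaging are linear, so their order is immaterial.

For the PLS, the complex values are first normalized to unit phasors; the
phase difference to the reference electrode is then formed by conjugate
multiplication (equivalent to subtracting phase angles — literal complex
subtraction would not yield a statistic bounded in $[0,1]$), and the
modulus of the trial mean is taken.  The reference is FCz for gamma and Cz
for alpha, both configurable.  Because the statistic is a resultant length
of $n$ phasors, its null expectation is not zero but the Rayleigh mean
$\sqrt{\pi}/2 \cdot n^{-1/2}$ (`pls_bias()`; the formula is asymptotic —
at $n = 2$ the exact value is $2/\pi$, 1.6 % above it).  Comparisons
between conditions with very different trial counts should either use the
bias as a reference point or equalize counts by seeded subsampling
(`equalize_to`), which is off by default to mirror the common practice of
analysing all artifact-free trials.

ROI extraction averages power and PLS over inclusive frequency grid points
(8–13 Hz: 6 bins; 28–50 Hz: 23 bins) and half-open time windows
(alpha 100–500 ms: 205 samples; gamma 200–400 ms: 103 samples at 512 Hz),
then over the montage's locations: the five midline electrodes
individually, and ten lateral regions (5 anteriority levels × 2
hemispheres, 3 electrodes each).  PLS is tabulated at lateral sites only,
since it is computed against a midline reference.  Plain means commute, so
averaging over frequency before time or vice versa is equivalent.

# The synthetic generator

The generator emulates the oddball study design so that recovery can be
tested against known truth: 512 Hz sampling; epochs of −300…700 ms (512
samples, half-open time axis $t_0 + k/f_s$); blocks of 1080 standards and
120 deviants (a 10 % deviant rate) in which the two analysed tones
(low-falling, high-rising) each occur as standard and as deviant across
blocks; groups of 10, 10 and 11 subjects (English, Chinese, Thai) over pre-
and post-training sessions.

Each trial is 1/f background noise (spectral synthesis, exponent 1, RMS
10 µV per channel) plus windowed sinusoids: an alpha component (10 Hz,
100–500 ms) and a gamma component (40 Hz, 200–400 ms) with 50 ms
cosine-squared ramps, so the injected amplitude is exact at the window
centre and spectral splatter stays inside the band.  The phase of each
oscillation is uniform per trial on its reference channel; every target
channel adds an independent von Mises$(0, \kappa)$ offset per trial.  This
coupling model is chosen deliberately: the expected PLS against the
reference is the closed-form Bessel ratio $I_1(\kappa)/I_0(\kappa)$, which
gives every phase-locking test an analytic oracle.  A fraction of trials
(0.18/0.24/0.26 for English/Chinese/Thai, matching the per-group rejection
rates the screening rule must reproduce) receives a 400 µV square spike on
one random channel so the peak-to-peak rejection filter has something to
find.

Condition structure is encoded as a multiplicative effects table over
(band × group × session × tone × condition): by default deviants carry
1.3× gamma and 1.2× alpha amplitude; after training the English group's
gamma amplitude rises 1.5× (the Chinese group's does not, the Thai's
1.2×), alpha amplitude falls to 0.8× for English and Chinese, and phase
coupling ($\kappa$) strengthens.  A per-subject lognormal amplitude factor
(SD 0.15 on the log scale, stable across sessions) supplies
between-subject variability.  **These settings are illustrative**: the
study the paradigm emulates reports statistics, not generative effect
sizes in µV, so the defaults are chosen once as qualitatively realistic
values that reproduce the *patterns* of interest — they are not estimates
of any real data set.  What the generator deliberately omits: volume
conduction and any forward head model (channels share phase structure only
through the von Mises coupling), acoustics of the stimuli, non-stationary
background rhythms, eye/muscle artifact morphology (spikes stand in for
all artifact classes).  Passing recovery tests therefore shows the
*analysis chain* is correct, not that real EEG satisfies its assumptions.

Determinism: every subject/session/block derives a child seed from the
master seed by an integer fold (`child_seed()`), so any subset of the
study can be regenerated in isolation and full runs are bit-reproducible.

# Statistics

`rm_anova()` implements the classical univariate mixed-design partition
for balanced fully-factorial repeated measures with one between-subjects
factor.  Per-subject cell means are projected onto orthonormal
within-subject contrasts (Kronecker products of per-factor orthonormalized
Helmert contrasts); each within stratum yields the within effect, its
interaction with the group factor, and the subject-interaction error term.
The decomposition reproduces `aov(... + Error(subject/...))` exactly
(tested), and is generated generically from the factor list because the
study's analyses use several factor subsets (midline vs lateral, pre-only
vs pre/post).

The GG epsilon is the standard sample estimator from the pooled
within-group covariance $S$ of the contrast scores,
$\hat\varepsilon = \mathrm{tr}(S)^2 / (d\,\mathrm{tr}(S^2))$, clamped to
$[1/d, 1]$; both numerator and denominator df are multiplied by
$\hat\varepsilon$.  It matches `car::Anova`'s value exactly (tested).  Two
choices deserve a note:

* the correction is applied only to effects with more than one numerator
  df — a two-level factor always reports $\hat\varepsilon = 1$;
* the corrected p is floored at the uncorrected p.  For $F < 1$ the raw GG
  recipe can *lower* the p-value (deflating both df shifts mass in the F
  distribution); since the correction exists purely to protect against
  liberal inference under non-sphericity, `wavepls` never lets it
  undercut the uncorrected test.  This only affects effects nobody would
  reject anyway.

Huynh–Feldt is intentionally out of scope.  Post-hoc group comparisons use
`bonferroni_pairwise()` (Welch tests between groups, paired tests within;
raw p × number of pairs, capped at 1).  `spearman_cor()` computes the
rank correlation with average ranks for ties, a two-sided t-approximation
p for $n \ge 10$ and an exact permutation enumeration below (the study
correlates ~20 subject-level band powers, squarely in the approximation
regime).  `follow_up_anovas()` slices the ROI table by group or location
after a significant interaction, with no alpha adjustment across
follow-ups, matching common practice.

# Validation harness and problem sizes

`type1_power_suite()` repeatedly generates a study, runs the full chain
(re-reference → rejection → wavelet → ROI → ANOVA) and tabulates rejection
rates with exact binomial confidence intervals.  The shipped validation
scenarios are scaled down so a complete run stays cheap on a single CPU;
the scaling choices are design decisions of this package:

* **Phase-locking recovery** uses 1 500 trials per $\kappa \in \{0, 0.5,
  1, 2, 4\}$ at high SNR, comparing pipeline PLS to
  $I_1(\kappa)/I_0(\kappa)$ within the Monte-Carlo band
  $3\sqrt{(1-\mathrm{PLS}^2)/n}$.
* **GG calibration** runs $10^4$ simulations of an 8-subject × 4-level
  spherical null, requiring a corrected type-I rate ≤ 0.06, plus a
  strongly non-spherical null where the uncorrected test visibly inflates
  and the corrected one does not.
* **End-to-end pattern recovery** uses 5 + 5 subjects (English, Chinese),
  one oddball block of 10 standards + 10 deviants per session, midline
  channels only, and a 3-Hz analysis grid across the gamma band (the 40-Hz
  kernel's $\sigma_f > 3$ Hz, so a 1-Hz grid is redundant for band means).
  With the default generator effects the test-time × group interaction on
  midline gamma power is detected in well over 80 % of 200 seeded
  replicates; with the training effects removed the rejection rate is
  compatible with the nominal 5 %.  The full-scale design (31 subjects,
  4 × 1200 trials, 39 channels, 1-Hz grid) runs through exactly the same
  code path.

# Degenerate inputs and numerical choices

* Zero complex values in phase normalization map to zero and are counted,
  never turned into NaN phasors.
* `reject_artifacts` with an infinite threshold masks nothing; a design
  where *all* trials are rejected is legal and simply fails screening.
* `screen_subject` checks that every tone × condition cell exists before
  applying the threshold, so an absent cell is an error, not a silent
  failure.
* EDF round trips are exact only to the 16-bit quantization step (physical
  range / 65534 per channel); the fixture dialect (raw doubles + JSON
  sidecar) is lossless and is what the pipeline uses internally.
* All seeds are folded into 31-bit integers, so any master seed a user
  passes on the command line stays within R's integer range.

# Known limitations

* The univariate partition assumes balanced within-subject designs;
  unbalanced cells must be aggregated or imputed upstream.
* PLS against a single reference electrode cannot distinguish genuine
  coupling changes from reference-site changes; this mirrors the analysis
  the package implements, and full sensor-pair connectivity is a declared
  non-goal.
* Scalp-level phase statistics are affected by volume conduction; the
  generator does not model it, so cross-condition *differences* are the
  only quantity the validation suite interprets.
* The EDF writer emits plain EDF (not EDF+ annotations); per-trial factors
  travel in the TSV sidecar.
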