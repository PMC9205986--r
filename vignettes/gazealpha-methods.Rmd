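---
title: "Methods: microsaccade detection, alpha lateralization, and permutation inference"
author: "gazealpha"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microsaccade detection, alpha lateralization, and permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazealpha)
```

## Scientific setting

Covert spatial attention leaves two measurable fingerprints: directional
biases in tiny fixational eye movements (microsaccades, typically below one
degree of visual angle), and a lateralized attenuation of posterior 8–12 Hz
EEG alpha power contralateral to the attended side. `gazealpha` implements a
joint analysis of the two in the retro-cue working-memory paradigm: two
items are encoded left and right of fixation at 5.7° eccentricity, a
non-spatial colour cue indicates which item to report, and gaze plus EEG are
analysed in a window around cue onset. Because the attended object exists
only in memory, any gaze bias is a pure reflection of internal attentional
selection.

The pipeline classifies each trial by the direction of the first detected
gaze shift in the 200–600 ms post-cue selection window (toward / away /
none / unusable), compares alpha lateralization between these classes, and
asks whether the timing of the alpha modulation co-varies with microsaccade
latency.

## Gaze pre-processing

* **Eye averaging.** Left- and right-eye channels are averaged samplewise; a
  NaN in either eye propagates, so blink stretches survive averaging.
* **Blink masking.** Every maximal NaN run is widened by 100 ms on each side
  to remove residual blink artefacts. Where two extensions overlap they are
  merged into a single run (an interval union). The alternative — applying
  the extension once per original run without merging — is
  indistinguishable in the masked output; the union formulation makes the
  operation idempotent, which is the property we test.
* **Calibration normalization.** A calibration recording visits seven
  points (left/right × top/middle/bottom at ±5.7°, plus the centre). Per
  position, the median cyclopean gaze in the 500–1000 ms after point onset
  is taken (the first 500 ms allow the saccade to the point to land), and
  an affine map from raw horizontal coordinates to percent units is fitted
  by least squares over the seven median points against their nominal
  values (centre = 0%, lateral columns = ±100%). After normalization ±100%
  means fixating an item centre and 1% = 0.057°. Least squares over all
  seven points is our choice of fit rule; with noiseless data it reproduces
  the nominal geometry exactly (the package's acceptance script
  demonstrates the identity), and medians make it robust to heavy-tailed
  segment noise.
* **Usability.** A trial is usable only if the masked trace has no NaN in
  the closed interval [0, 600] ms. Closing both ends is the conservative
  reading (more trials flagged unusable).

## Gaze-shift detection

Velocity is the absolute first difference of the normalized horizontal
position (%/ms at 1 kHz), smoothed with a Gaussian-weighted moving average
over a 7-ms window. The Gaussian's width is window/5 (≈1.4 samples),
truncated to the window — the common default for Gaussian-weighted moving
averages; it is configurable. NaN samples poison the kernel support, so
velocity is undefined across blinks and events cannot straddle them.

Candidate onsets are the first samples of runs exceeding a deliberately low
trial-based threshold of **3 × the median smoothed velocity** over all
finite samples of the epoch (the full epoch gives the most stable median
under the null of fixational drift; using the smoothed velocity for the
median keeps threshold and signal on the same scale). A refractory rule
keeps only onsets more than 100 ms after the last *kept* onset; suppressed
crossings do not restart the period. Shift magnitude is the mean position
in [onset+50, onset+100] ms minus the mean in [onset−50, onset] ms (closed
windows, finite samples only); events with |magnitude| < 1% (0.057°) are
discarded — the low velocity threshold deliberately over-detects, and the
magnitude floor removes drift-induced false alarms. Onsets whose magnitude
windows would leave the epoch are skipped and logged.

One subtlety of this rule ordering (refractory between retained crossings,
magnitude floor afterwards) is that the final event count is not monotone
in the threshold multiplier: raising the threshold can remove an early
sub-floor crossing that consumed the refractory window, letting a later
large shift through. The monotone property — a shrinking supra-threshold
set — holds at the candidate-crossing stage, and that is the stage at which
the package tests it.

Trials are classified by the direction of the first detected shift with
onset in [200, 600] ms: *toward* when the signed magnitude points to the
cued item's memorised side, *away* otherwise, *none* when no in-window
shift exists. Rate time courses use a 50-ms sliding window in 1-ms steps
(we centre the window, half-open `[t−25, t+25)`), and the time × magnitude
decomposition uses overlapping 5%-wide magnitude bins with left edges
1–110% in 1% steps; bin *b* covers `[b, b+5)` in absolute magnitude (the
half-open convention is fixed and documented because the graphical source
of this representation does not pin it down).

The Engbert–Kliegl detector is provided as the established alternative:
5-point moving-derivative velocity in both axes and both eyes, an elliptic
threshold of λ = 6 median-based velocity SDs per axis, minimum duration
6 ms, and ≥1 sample of binocular overlap (all configurable). Its events are
mapped into the same event table (same magnitude rule, floor, and
refractory separation) so downstream stages are detector-agnostic.

## Alpha lateralization

Spectral power is estimated with a short-time Fourier transform of
Hann-tapered 300-ms windows, 1–50 Hz in 1-Hz steps, advanced in 50-ms steps
(1-ms steps in the latency analysis, where temporal resolution matters).
Numerical choices:

* The 300-ms window is zero-padded to 1 s so that the 1-Hz frequency grid
  falls on exact DFT bins. The transform is computed as a single matrix
  product of the stacked windows with a complex kernel; this is
  algebraically identical to a per-window padded DFT at any hop, so the
  50-ms and 1-ms modes agree exactly on shared time points (a unit test
  asserts this).
* Windows that would extend past the epoch are dropped, not padded.
* Power is not normalized by taper energy: the contrast below is scale
  invariant, so the factor cancels.

Lateralization is the normalized contrast
`((contra − ipsi) / (contra + ipsi)) × 100`, bounded by ±100 and
antisymmetric under channel exchange. Power is averaged across trials
within a condition *before* the contrast is formed (the
contrast-of-averages reading); averaging per-trial contrasts instead is
available via `per_trial_contrast = TRUE`, and on synthetic data the two
estimates agree in sign and magnitude. The alpha time course is the
unweighted mean over the 8–12 Hz rows. Real 61-channel recordings would
first be reduced to left/right posterior cluster averages; the synthetic
generator emits those two cluster channels directly, so the cluster
averaging (and the surface Laplacian that precedes it on real data) is an
identity here — `condition_alpha_timecourse()` accepts any per-trial
two-channel representation.

## Statistics

**Cluster-based permutation test.** Mass-univariate t-tests at a two-sided
alpha of 0.05 define supra-threshold points; adjacent same-signed points
form clusters (4-neighbour adjacency on time × frequency grids, no
diagonals); cluster mass is the sum of t-values; the permutation
distribution collects the largest absolute mass under participant-level
sign flips (one-sample) or condition swaps (paired — implemented as sign
flips of the paired differences, to which it is algebraically identical).
Because the cluster-forming threshold is two-sided, observed clusters are
compared by absolute mass. When 2^n does not exceed the requested 10,000
permutations the test enumerates all sign flips and reports exact
proportions (the identity relabelling keeps p strictly positive);
otherwise random flips are drawn and p = (b+1)/(B+1), which can never be
zero. Degenerate zero-variance points carry t = 0 rather than NaN.

**Half-peak latency.** The latency of the alpha modulation is the first
time its grand-average time course reaches half of its peak (most negative)
value, linearly interpolated between the 1-ms samples for sub-sample
stability. The default search window is 0–1000 ms post-cue; the modulation
of interest develops well within this range, and the window is
configurable. The early/late comparison swaps condition labels within
random participant subsets, recomputes the half-peaks **on the permuted
grand averages** (the same computation as the observed statistic), and
reports the one-sided proportion of permutations with a latency difference
at least as large as observed — one-sided because the median split
predicts the direction; a two-sided option exists. Permutations with an
undefined half-peak are dropped; more than 5% of them aborts the test with
a diagnostic.

**Behaviour.** Reaction times above 3000 ms are removed first; then trials
beyond 2.5 SD from the participant's mean RT (computed on the first step's
survivors). Class comparisons use a one-way repeated-measures ANOVA over
the toward/none/away cell means with partial η², plus Bonferroni-corrected
two-sided paired t-tests with Cohen's d for paired samples.

Both `trim_behaviour()` and `mask_blinks()` tag their output (an attribute)
and return already-processed input unchanged. This matters because neither
operation is naturally idempotent — re-estimating the SD criterion on
trimmed data would silently tighten it, and re-extending merged NaN runs
would widen them — and accidental double application is a real hazard in
interactive use.

## The synthetic-study generator

The generator emulates the statistical structure of the study so that every
stage can be validated by parameter recovery. Defaults are fixed once, from
the study conditions where stated and by modelling judgement otherwise:

* **Design:** 23 participants × 1200 trials, cued sides balanced, items at
  5.7°, epoch −1000..+2000 ms at 1 kHz.
* **Shift plan:** a trial contains an in-window shift with probability
  0.66 (the observed 44% toward + 22% away of usable trials), and the first
  shift is toward with probability 2/3 (= 44/66). First-shift latency is a
  truncated normal on [200, 600] ms with mean 400 and SD 110 ms —
  back-derived so that a median split reproduces early/late class means
  near 324/473 ms. Magnitudes are lognormal (median 5%, log-SD 0.6,
  floored at 1%), putting almost all mass below 1° (17.5%); the magnitude
  distribution is only reported graphically in the source literature, so
  these are modeller's choices. A quarter of trials get one extra late
  shift (after 720 ms), emulating multi-shift trials without touching the
  selection window.
* **Waveform and noise:** shifts are minimum-jerk steps of 20 ms (any
  smooth monotone step suffices for detector testing); fixational drift is
  a Gaussian random walk (0.03%/√ms, ≈0.1° over a trial); per-eye white
  measurement noise 0.1%; blinks are Poisson (0.2/trial) NaN stretches of
  100–300 ms.
* **EEG:** two cluster channels with 1/f background noise (slope 1, SD 1)
  plus a 10 Hz oscillation of amplitude 2; after the modulation onset the
  contralateral amplitude ramps down (cosine ramp, 100 ms) by depth 0.3.
  The modulation onset is the first in-window shift onset + 50 ms, making
  alpha timing co-vary with microsaccade latency; in no-shift trials it is
  the mean latency + 50 ms, so the no-shift class carries modulation
  equivalent to shift trials — the generator's way of encoding the finding
  that attention modulates alpha with or without microsaccades. Away-class
  trials receive half the depth (`alpha_away_factor = 0.5`), encoding the
  attenuated modulation when the first microsaccade goes the wrong way.
* **Behaviour:** reproduction error is Normal per class (means 13.65 /
  14.2 / 14.72° for toward / none / away, SD 6°, clamped at 0); RT is
  class-independent Normal (900 ± 250 ms).
* **Reproducibility:** random streams are split per participant and per
  trial (each trial is generated under its own derived seed), so
  regenerating a subset reproduces the same data byte for byte.

With zero noise the generator admits closed forms: a modulation depth *d*
leaves the contralateral amplitude at (1−d), so band power scales by
(1−d)² and the plateau lateralization is ((1−d)²−1)/((1−d)²+1) × 100 — for
d = 0.5 exactly −60%. The measured plateau deviates from −60 only through
negative-frequency leakage of the finite Hann window (≲0.05 percentage
points), which is why recovery is tested to ±0.6.

**What the generator does not emulate:** volume conduction and topography
(EEG exists only at the two-cluster level), oculomotor dynamics (main
sequence, drift–tremor structure, vertical attention effects), non-
stationary alpha (the oscillation is a fixed-frequency sinusoid), and any
dependence of behaviour on RT class. Passing recovery tests therefore
demonstrates the correctness of the analysis logic under the modelled
structure, not performance on real recordings.

## Problem sizes and determinism

The test suite and worked examples run the pipeline at reduced scale —
typically 3–10 participants with 12–200 trials and epochs of 1–3 s — which
is ample for the closed-form identities, oracle-equivalence checks, and
binomial/permutation calibration properties being tested; the generator's
defaults remain the full study conditions. Permutation tests in examples
request 400–2000 permutations and switch to exhaustive enumeration
whenever 2^n is smaller. All analyses are deterministic given the study
seed: `run_study_analysis()` re-seeds from the study configuration, so
identical inputs give byte-identical serialized reports.

## Known limitations

* The velocity detector is horizontal-only by design (the attention axis
  is horizontal); purely vertical microsaccades are invisible to it. The
  Engbert–Kliegl detector covers that case.
* Half-peak latencies are undefined for flat time courses; the latency
  test propagates this as an explicit error rather than guessing.
* The repeated-measures ANOVA assumes sphericity; with three conditions
  and the package's use case (a directional F plus planned paired
  contrasts) no sphericity correction is applied.
* `read_study()`/`write_study()` use a plain CSV/JSON layout; large
  studies are better regenerated from their configuration (a few integers)
  than stored.
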