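---
title: "Methods: simulated kinesthetic-illusion motor-imagery EEG and its analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated kinesthetic-illusion motor-imagery EEG and its analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(kibci)
```

## The problem this package addresses

Lower-limb motor imagery (LMI) drives brain-computer interfaces for gait
rehabilitation, but the lower-limb cortical representation is small and
mesial, so many users produce weak, hard-to-decode sensorimotor rhythms.
One remedy is to pair imagery with a kinesthetic illusion (KI): vibrating
the Achilles tendon creates an illusory sense of limb movement that
recruits the same sensorimotor cortex. A study of this paradigm records
16-channel EEG over the sensorimotor strip while subjects perform four
cued conditions — quiet rest, rest with vibration (V-rest), imagery alone
(no-LMI) and imagery with vibration (KI-LMI) — and then quantifies the
illusion's effect through event-related desynchronization (ERD),
imaginary-coherency connectivity, and filter-bank common spatial pattern
(FBCSP) classification.

`kibci` re-implements that complete analysis chain as a tested, reusable
package. Because no raw EEG from such studies is bundled, the package's
first module is a synthetic-session generator that reproduces the
paradigm's structure and the signal phenomena the analysis assumes, so
every downstream stage can be exercised and validated end to end.

## The paradigm and the generator

A session is 12 runs of 16 trials (4 per condition per run by default,
192 trials total). Each trial is a fixed 10.5-s slot: 2 s fixation
cross, 1 s text cue, 3.5 s task, 4 s relaxation. All timing is
configurable (`sim_config()`); the trial schedule is shuffled uniformly
within each run (`build_trial_schedule()`).

Each channel is synthesized as

* a `1/f` background (default exponent 1, 5 uV RMS, flat below 1 Hz),
* an alpha (8-13 Hz) and a beta (14-30 Hz) narrowband oscillation
  (defaults 10 and 5 uV RMS).

The two rhythms are modelled as *constant-envelope* oscillations: the
instantaneous phase of a band-limited Gaussian process with the envelope
fixed. This is a deliberate design choice. The ERD estimand is a
fractional band-power change measured against a 1-s baseline over 40
trials; with Rayleigh-fluctuating (Gaussian-process) envelopes the
chi-square-like variance of short-window power estimates would dominate
the quantity the analysis is supposed to measure (the estimator's SD at
those sizes is ~4 percentage points), whereas with a stabilized envelope
the injected depth is identifiable at the paradigm's own window sizes.
The 1/f background still supplies realistic broadband, in-band power
fluctuation. Real EEG alpha does wax and wane; what the simulation keeps
is the spectral structure, the time-locked modulation, and the
multichannel geometry — not envelope statistics.

ERD is injected multiplicatively: during a trial's task segment, the
rhythm amplitude at a channel with configured depth `d` for that trial's
condition is scaled by `sqrt(1 - d)` (a fractional power drop of `d`),
ramping linearly over `erd_latency` (default 0.5 s) to reproduce the
gradual descent of empirical grand-average ERD traces. Default depth
profile: rest 0 everywhere; V-rest a slight 0.05 at Cz/CPz (vibration
alone weakly engages the mesial cortex); no-LMI 0.30 at Cz, 0.20 at CPz,
0.15 at C1/C2; KI-LMI deeper and more contralateral — 0.45 at Cz, 0.35
at CPz, 0.25 at C1/C2, 0.15 at C3. These defaults were chosen once to
put the simulated Cz ERD minima in the range empirical traces show
(roughly -30 to -50%), with the illusion condition deeper than imagery
alone.

The montage is a 10-10 sensorimotor grid (FC3..FC4, C5..C6, CP3..CP2);
Cz overlies the lower-limb representation. Optional extras: half-sine
"blink-like" transients (0.3 s, default 300 uV) injected into the
frontocentral row of a Bernoulli subset of trials, to exercise artifact
rejection; and a lagged shared narrowband source between two channels
(off by default) so that imaginary-coherency contrasts are testable.

What passing tests on this generator shows: the analysis code computes
the quantities it claims — power ratios, spectra, eigenproblems,
cross-validated accuracies — correctly on signals with known ground
truth. What it does not show: robustness to real-EEG nuisances (volume
conduction from deep sources, non-stationary artifacts, electrode drift,
inter-subject variability), which no desk-scale simulation certifies.

Sessions round-trip through a minimal EDF writer/reader (16-bit,
one-second records, symmetric digital range so quantization is exactly
invertible up to half an LSB) plus a JSON sidecar holding the schedule,
montage and seed. The writer is cross-checked in the test suite against
an independent EDF implementation.

## ERD quantification

The classical ERD pipeline: band-pass filter every trial, square the
samples, average across trials, smooth over a 0.25-s moving window
(dense one-sample hop, truncated windows dropped at segment edges).
Baseline power `P_base` is the time average of the trial-averaged power
over the baseline window (t = -2.5 to -1.5 s before task onset, inside
the fixation period); the task window is t = 0.5 to 3.5 s (the first
half-second after the cue is skipped as transient-contaminated). Then

* `ERD(t) = (P_t - P_base) / P_base x 100` (instantaneous, in %),
* mean ERD `= (P_task - P_base) / P_base x 100` with `P_task` the task-
  window time average — the per-channel scalar used for topographies and
  channel statistics.

The order of operations matters: powers are averaged across trials
*before* normalization. A property test documents that normalizing each
trial first and then averaging gives a different number on
heterogeneous-amplitude trials, guarding against silent reordering.

Filtering is a 4th-order Butterworth applied zero-phase. Numerically we
apply the squared magnitude response on the FFT grid of the whole stored
trial segment (t = -3 to +4 s) after odd-reflection padding — the
frequency-domain form of forward-backward filtering — because the
startup transient of a time-domain pass over a short window deflates
power exactly where the baseline sits. Agreement with time-domain
`filtfilt` away from edges is at the 0.3% level; the FFT form also lets
all trials be filtered in one `mvfft` call.

Summary statistics for ERD traces: `e_min` (the minimum over the task
window) and the arrival time (first time the trace reaches a reference
level — its own minimum, or another condition's minimum when comparing
imagery with and without the illusion). A reference never reached is
reported as `NA` with `reached = FALSE`, not an error.

`relative_power_db()` computes `10 log10` of the power ratio between a
condition and a reference condition (or the own baseline). Note the
scale: a 21% power drop is about -1 dB. Published grand-average figures
sometimes show tens of dB for comparable conditions, which cannot be
derived from the percent-ERD definition; the decibel output here is a
clearly named alternative quantity and no figure-scale value is asserted
anywhere in the package.

## Imaginary coherency

Connectivity uses the imaginary part of coherency,
`iCOH(f) = Im S_xy(f) / sqrt(S_xx S_yy)`, chosen for its insensitivity
to zero-lag (volume-conducted) mixing: an instantaneously mixed source
contributes a purely real cross-spectrum, so a channel pair can show
coherence near 1 and |iCOH| near 0 — a property the test suite checks
explicitly. Spectra are estimated Welch-style with each 3-s Hann-tapered
task epoch as one segment (~0.33 Hz resolution), averaged across trials;
at least two trials are required since single-segment coherence is
identically 1. The band summary is the mean of `|Im R|` over in-band
bins — absolute value before averaging, since connectivity maps plot
connection strength; the signed band mean (antisymmetric across the
matrix) is retained for diagnostics. Grand averages are elementwise
means over sessions. Which of signed or absolute band averaging a given
study used is typically undocumented; both are exposed here with
absolute as the default.

## FBCSP + SVM classification

The four evaluation pairings are D1 rest/V-rest, D2 rest/no-LMI, D3
rest/KI-LMI, D4 V-rest/KI-LMI, each 40 trials per class after artifact
rejection and seeded subsampling.

The feature pipeline: six 4-5-Hz sub-bands spanning 7-32 Hz; per band,
common spatial patterns from the two-class generalized eigenproblem on
trace-normalized average covariances (Cholesky whitening of the
composite covariance + symmetric eigendecomposition; filters normalized
so `W (S_a + S_b) W' = I`; deterministic sign and eigenvalue-then-index
ordering); 2 filter pairs per band (4 components, 24 pooled candidates);
per-trial log-normalized-variance features; mutual-information selection
of the top 8. The MI estimator is an equal-frequency histogram
(Sturges-style bin count) — feature selection only needs a ranking, and
equal-frequency bins are robust to the heavy tails of log-variance
features. Ties break toward the lower feature index.

Evaluation is stratified 5-fold cross-validation with *nested* tuning:
within every outer training fold, the entire pipeline (CSP, MI
selection) is refitted on each inner 3-fold split before the RBF-SVM
grid search over `C in 2^{-3..7}`, `gamma in 2^{-7..3}` (alternate
powers of two across the stated ranges; ties prefer the smaller `C`,
then the smaller `gamma`). Whether published analyses nested the
hyperparameter search is usually unstated; nesting is the leakage-free
choice and the one implemented. Band-pass filtering and per-trial
covariances are computed once per dataset and shared across folds —
both are label-free, trial-wise operations, so this is a pure
optimization, not leakage; a property test verifies that permuting a
held-out fold's labels cannot change that fold's predictions.

Fold confusion counts are pooled before the accuracy/F1 formulas
(`Acc = (TP+TN)/total`, F1 the harmonic mean of precision and recall,
both in %); per-fold metrics are also retained. F1 is `NA` (a sentinel,
not an error) when precision or recall is undefined.

## Group statistics

`aggregate_scores()` is a plain mean/SD over subjects with rounding only
at the reporting boundary. `paired_ttest()` and `one_sample_ttest()`
(two-sided; chance level 50% for balanced pairs) are gated by a
Shapiro-Wilk normality check: failing data routes to a Wilcoxon
signed-rank fallback, flagged in the `method` field as a divergence from
a plain-t report. Degenerate inputs follow explicit conventions:
identical paired vectors give t = 0, p = 1; a zero-variance nonzero
shift is reported as degenerate with `NA` statistics. Significance stars
are reported at 0.05/0.01/0.001 alongside exact p-values. No
multiple-testing correction is applied by default (matching how such
channel-by-band tables are usually reported); `group_report(holm =
TRUE)` enables a Holm correction.

The package ships a transcribed reference table of per-subject F1
scores (16 subjects x 3 pairings) as a worked aggregation example; its
row means, the offline improvement from adding the illusion (+7.6
points), and the 11-subject "improved" subset means are reproduced
exactly by `aggregate_scores()` in the acceptance tests. That source
also describes six below-70% subjects but then refers to "these five
subjects"; the six-ID list is stored and the inconsistency is surfaced
here rather than resolved.

## Problem sizes and numerical conventions in the test suite

Simulation-based tests run at 160 Hz sampling (all analysis bands sit
below 32 Hz) with 40 trials per condition — the per-condition count the
analysis itself prescribes — and fixed seeds throughout; the generator's
paradigm defaults (1200 Hz, 192 trials) are exercised where the property
under test is the paradigm bookkeeping itself. ERD recovery is checked
in the 8-30 Hz band used for Cz trace analysis (its wider bandwidth
gives the estimator ~4x more degrees of freedom than alpha alone).
Chance-level classification is averaged over three label permutations
because a single cross-validated run at chance has an SD of ~6
percentage points and a slight pessimistic bias. Other conventions:
peak-to-peak rejection uses a strict `>` at 200 uV (kept at exactly
200.0); epoch windows are half-open `[start, end)`; the ERD floor -100%
follows from nonnegative power; CSP covariances receive trace
normalization and, only if rank-deficient, logged shrinkage.

## Known limitations

* The generator does not model volume conduction, realistic
  EOG/EMG morphology, electrode drift, or inter-subject variability;
  artifact injection is amplitude-threshold-level only.
* The visual-inspection arm of artifact rejection cannot be automated;
  only the quantitative peak-to-peak rule plus a pluggable predicate is
  provided.
* Decoding accuracies obtained on synthetic sessions depend on the
  configured depth profiles and are not calibrated to any human
  subject's numbers; only directional claims (deeper ERD -> higher
  accuracy, illusion condition deeper than imagery alone) are asserted.
* The decibel relative-power output is a distinct quantity from percent
  ERD and is not reconciled with figure scales that lack a stated
  formula.
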