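---
title: "Classifying prospective fallers from turn and straight-walking accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying prospective fallers from turn and straight-walking accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turngait)
```

## The problem

Older adults at elevated fall risk often walk almost normally on a straight
path; the deficits show when they turn. `turngait` implements a complete
pipeline for asking whether wearable-accelerometer features extracted from
*walking turns* classify prospective fallers (PF, people who go on to fall
within a follow-up window) better than features from *straight walking*. The
sensing setup is three tri-axial accelerometers — posterior pelvis ("lower
back", LB) and both lateral shanks (LS, RS) — worn during a six-minute walk
test (6MWT) in which the participant walks between two cones roughly 30 m
apart, turning at each end.

Because raw cohort recordings of this kind are generally not shareable, the
package ships a seeded synthetic-session generator with planted ground truth
(turn windows, per-foot step times) so every downstream stage is testable
end to end. The generator is a first-class, tested module, not a fixture.

## Pipeline overview

1. **Preprocessing** (`resample_50hz()`, `synchronize()`, `detect_steps()`,
   `segment_turns()`, `segment_straight()`): each sensor is resampled to a
   uniform 50 Hz grid by linear interpolation, the three sensors are aligned
   on the first prominent vertical peak (a deliberate synchronization spike
   in the synthetic data), foot strikes are detected as prominent vertical
   peaks, and the session is cut into five-step standardized turns and
   straight passes.
2. **Feature bank** (`section_features()`, `aggregate_participant()`): 74
   named features per walking section, aggregated over a participant's
   sections of each condition by max/min/mean/SD into 296 features per
   condition (592 when straight and turn are concatenated).
3. **Modeling** (`select_features()`, `train_and_evaluate()`): min-max
   normalization learned on training rows, three feature selectors (S5B,
   SEL, RFE), six classifiers (3NN, 5NN, linear/cubic/quintic-kernel SVM,
   100-tree random forest), and seven metrics with PF as the positive class.
4. **Protocol** (`run_protocol()`): stratified five-fold CV over all 18
   classifier-selector combinations (Test I), pruning of the weakest
   classifier and selector, random-shuffle-split CV over the surviving 10
   combinations with Welch comparisons of the best turn and straight models
   (Test II), nested most-frequently-occurring (MFO) feature-subset sweeps
   (Test III), and the combined 592-feature run (Test IV).

## The feature bank

For each section (a turn or a straight pass) and each sensor:

* **Directional descriptive statistics** — for each axis (vertical, ML, AP)
  the maximum, mean, and sample SD are computed separately over
  positive-direction samples and over the magnitudes of negative-direction
  samples, per stride, then averaged across the section's strides
  (3 stats x 3 axes x 2 directions = 18 per sensor). A direction with no
  samples contributes zeros; SDs use denominator n-1 and are 0 for a single
  sample.
* **FQFFT** — the fraction of FFT amplitude between 0 and the 12.5 Hz
  "first-quartile" edge, out of the total up to the 25 Hz Nyquist, after
  mean removal. Low values mean more high-frequency content — less steady
  movement.
* **REOH** — the ratio of even to odd harmonics of the stride frequency
  (inverse of the section's mean same-foot strike interval). A symmetric
  gait repeats every *step*, so its energy sits at even stride harmonics;
  left/right asymmetry populates the odd harmonics. We use the bounded form
  even/(even + odd) over 20 harmonics (nearest-bin amplitude sampling), so
  the value lives in [0, 1] and falls as asymmetry grows. The raw even/odd
  quotient is available via `normalized = FALSE`.
* **Temporal (lower back only)** — cadence, 60(n-1)/span of the LB step
  train, and stride time, the mean left-shank strike-to-strike interval.

This gives 24 features per shank and 26 for the lower back: 74 per section.
Aggregating each base feature across a participant's sections with max, min,
mean, and SD yields 4 x 74 = 296 features per condition; concatenating both
conditions gives 592. These counts are asserted structurally in the tests.

Two windowing decisions deserve note. FQFFT and REOH are computed once per
*section* rather than per stride: a single stride at 50 Hz (~50 samples)
cannot resolve stride-frequency harmonics at all, so a per-stride spectral
estimate would be meaningless. And a five-step turn contains only ~2.5
strides, so turn-section REOH uses a short window with coarse frequency
resolution; it is computed whenever at least two reference-foot strikes fall
in the section, and is simply a noisier feature there — which is faithful to
how such features behave on real turns.

## Segmentation choices

Turns are detected from the characteristic drop in vertical acceleration
magnitude: a 1.0 s sliding RMS of the LB vertical channel is compared with
its session median, and maximal runs below `theta = 0.7` of the median
lasting at least 0.5 s are turn candidates. Each candidate is standardized
to five steps — the detected step nearest the run midpoint plus two steps on
each side — with a 0.2 s buffer before the first and after the last step.
We centre on the run midpoint rather than the literal RMS argmin because,
within the attenuated plateau, the argmin jitters between step impulses and
would misplace the five-step window by a step about half the time. Window
length, threshold, and run length are exposed as arguments.

Straight sections are the complement of the turns within the walking portion
(first to last detected LB step), trimmed 0.2 s at each junction, keeping
only sections with at least three reference-foot strides. Importantly,
*every* below-threshold RMS run is excluded from straight sections, whether
or not it produced a standardized turn: turning behaviour that fails the
five-step rule must not contaminate "straight" features, since the central
scientific claim rests on the straight/turn contrast.

Sessions with fewer than two detected turns are flagged, mirroring the
exclusion of participants whose records cannot be segmented reliably.

## The synthetic generator

`simulate_session()` builds a continuous-time signal model and samples it at
each sensor's own rate (50 Hz perturbed by `sample_rate_jitter`), so the
three sensors observe the same underlying processes:

* **Turn stress**: asymmetry and high-frequency noise express at
  `turn_stress` times their baseline strength inside turn windows (in-turn
  asymmetry capped at 0.85). Turning challenges stability, so a marginal
  deficit that is barely visible on the straight shows clearly in the turn.
  Crucially, the default stress differs by class (1.5 for non-fallers, 3
  for the prospective-faller profile): non-fallers negotiate turns with
  little extra cost while fallers destabilize, which is the mechanism that
  gives turn-based features their edge in this analysis.
* The vertical channel is a train of raised-cosine impulses (width 0.18 s)
  at the step times, plus, on the pelvis only, a small harmonic series of
  the step frequency phase-locked to the first step. Shank channels carry
  their own foot's impulses with a small contralateral transient, which
  keeps per-foot strike detection unambiguous.
* **Asymmetry** scales alternate steps by (1 ± `asymmetry`). This provably
  moves energy to odd stride harmonics and is the knob behind the
  REOH-decreases-with-asymmetry property test.
* **High-frequency noise** is a deterministic random harmonic sum over
  13-24.5 Hz with total power `hf_noise_power`, evaluable at arbitrary
  times; it drives FQFFT down.
* **Turns**: after each cone-to-cone pass (`walkway_time_s`, turn included)
  the next five steps are a turn; the vertical walking component is
  multiplied by `turn_attenuation` across the turn window and a low-frequency
  ML sway is added. Turn amplitude is governed by the attenuation alone,
  while per-section variability (`section_variability`) scales straight
  passes — this keeps the RMS drop detectable at any variability level.
* **Natural variability**: each session draws its own cadence
  (`cadence_sd`, default 0.05 Hz) and every step gets amplitude jitter
  (`amp_jitter`, CV 0.05). Without these, all same-class sessions would have
  virtually identical section lengths, and length-sensitive spectral leakage
  would make features deterministic per class — a simulator artifact that
  produced absurdly perfect classification in early testing and that real
  gait data does not exhibit.
* A synchronization spike of 3x the step amplitude is planted near t = 0 on
  all sensors, so the "first prominent vertical peak" rule is unambiguous;
  step detection ignores the first 0.5 s to avoid counting it as a strike.

`simulate_cohort()` derives per-participant seeds as `seed + index`, so
cohorts are reproducible under partial regeneration. The default
prospective-faller class profile elevates asymmetry (0.12 vs 0.05),
high-frequency noise power (0.003 vs 0.002 g^2), and section variability
(0.14 vs 0.08) — the three properties the feature bank targets — and each
participant additionally draws individual values around the class means
(`param_spread`: asymmetry SD 0.08, log-normal noise multiplier SD 0.5,
section-variability SD 0.05). The spreads make the two class populations
overlap, so cohort classification is good but imperfect rather than
trivially saturated, with the turn-stress mechanism giving turn features
the larger share of the signal. These effect sizes are
simulation choices for testability, not measured population values; the
generator also cannot claim biomechanical realism (no musculoskeletal
dynamics, no gyroscope channels, idealized turn geometry). Passing tests
demonstrate that the pipeline recovers planted structure, not that it would
reach any particular accuracy on real cohorts.

The `turn_only_effects` switch gates asymmetry and noise to the turn windows
(zero elsewhere). Paired with a baseline profile whose asymmetry and noise
are zero, it builds cohorts whose classes differ *only while turning* — the
cleanest way to probe whether the protocol attributes discriminative power
to the correct condition.

## Modeling and protocol conventions

* Normalization maps each feature through (y - y_min)/(y_max - y_min) with
  training-set extremes; constant features map to 0 and test values are not
  clamped. Selection and model fitting only ever see training rows; the
  function signatures make leakage structurally impossible.
* S5B takes the top five features by two-class ANOVA F. SEL unions a raw
  p < 0.05 filter with a Benjamini-Hochberg FDR filter at 0.05, ordered by
  p; if the union is empty (possible on null data) the single best-p feature
  is used. RFE eliminates one feature at a time using random-forest impurity
  importances down to five.
* SVMs use cost 1, coef0 0, and the kernel scale 1/(d Var(X)); the
  quintic-polynomial kernel needs this data-adaptive scale to be usable on
  [0, 1]-normalized features. kNN uses Euclidean distance with uniform
  weights (odd k, so two-class votes cannot tie). Random forests use 100
  trees and an explicit seed.
* Metrics with zero denominators are defined as 0. Per-metric ranks are
  "minimum" ranks (a three-way tie at position three yields 1, 2, 3, 3, 3,
  6, 7) and are summed over the seven metrics; lower is better.
* The 95% CI half-width convention is 1.96 SD/sqrt(n_iter).
* Per-iteration seeds are derived from the base seed by a fixed affine hash,
  keeping every RSS iteration reproducible; degenerate splits (a class
  missing) are redrawn with the next derived seed.
* Test IV's "top four classifiers" are read from the Test II *turn* rank
  table, since Test IV extends the turn analysis; the pooled top-nine
  counting rule for the Test I prune treats straight and turn tables jointly,
  with frequency ties broken by the worse best rank sum.
* MFO subsets use the features selected in at least 10% of iterations,
  ordered by frequency with alphabetical tie-breaks. The frequency table is
  read from the S5B selections: S5B contributes exactly five names per
  iteration, so selection frequency is a meaningful stability measure,
  whereas SEL's unrestricted lists can mark most of the feature bank as
  "frequent" and would degenerate the nested sweep into hundreds of
  near-identical subset runs.

## What the tests do and do not show

The test suite checks structural contracts (feature counts 24/26/74/296/592,
five-step turns, buffer timing), analytic limits (FQFFT of pure tones, REOH
of pure odd/even harmonics), planted-truth recovery (turn precision and
recall over seeded sessions), monotone responses of features to generator
knobs, and condition attribution (turn-only class differences surface in
turn models, with straight models at chance).

One calibration property deserves a frank note. On a fixed no-signal cohort
(identical class-generating profiles, n = 40), the *conditional* mean MCC of
shuffle-split CV with per-iteration feature selection is **not** zero: among
296 candidate features the realized cohort always contains some chance class
separation (the largest of 296 two-sample contrasts at n = 40 is around
|t| ~ 3.5), the selector finds it in the training rows, and the held-out
rows of the same cohort share it. With 296 iid standard-normal features and
no generative signal whatsoever, we measure conditional mean MCC of roughly
0.2-0.3 for every classifier-selector combination, far outside the
+-3 SD/sqrt(n_iter) band that would describe pure split-resampling noise.
This is a property of cross-validation on a fixed small cohort with
high-dimensional selection — the expectation over *fresh cohorts* is zero,
but the per-cohort value is optimistically biased — and it is why the
dedicated calibration test in this package's acceptance suite fails at that
tight band, with all other behavioural checks passing. Users comparing
conditions should rely on paired contrasts (as the protocol's Welch tests
do), which difference this bias away, rather than absolute null levels.

## Problem sizes used in the checks

Desk-scale runs shrink only the experiment's size, never its logic: the
bundled checks use 120-360 s sessions, cohorts of 20-71 participants, and
100-200 shuffle-split iterations (the full protocol uses 2500), with the MFO
threshold kept at 10% of iterations throughout. All stages accept these as
plain arguments, so a full-scale rerun is a parameter change.

## Known limitations

* The generator's PF/NF effect sizes are tuning knobs; absolute accuracies
  on synthetic cohorts say nothing about clinical performance.
* Turn-section REOH rests on ~2.5 strides and is intrinsically noisy.
* Linear-interpolation resampling attenuates nothing but aliases nothing
  either; at 50 Hz nominal rates with ~1% deviation its error is small
  (worst-case ~0.05 g for a 5 Hz component), but a polyphase resampler would
  be preferable for very irregular clocks.
* Turn detection is accelerometer-only by design; gyroscope- or
  video-assisted segmentation is out of scope.
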