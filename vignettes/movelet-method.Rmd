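---
title: "The multistream movelet method: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multistream movelet method: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moveletr)
```

## The method

The movelet method is personalized, nonparametric activity recognition by
nearest-neighbor matching of short raw signal windows. It assumes that
(i) a person's execution of an activity is stereotyped enough that a
fresh 1-s window of the activity resembles *some* 1-s window of that
person's own training bout, and (ii) the training bouts, though short
(seconds), cover the activity's within-person variability. No filtering,
normalization, or feature extraction is applied; the raw sample values
are the representation.

**Dictionary.** For each activity, every window of `window_samples`
consecutive samples of the training segment, advanced one sample at a
time, is stored as a labeled movelet. A segment of `N` samples yields
`N - window_samples + 1` movelets; consecutive movelets share all but one
sample. At the canonical 10 Hz with 1-s windows, 5 s of training yields
41 movelets per activity.

**Matching.** A test movelet is compared against every dictionary movelet
(exhaustive scan; dictionaries are a few hundred movelets, so indexing
would buy nothing) by the discrepancy metric: the per-channel Euclidean
distance, averaged over channels. The same formula serves the
single-sensor metric (3 channels) and the joint-sensor metric
(6 channels); no unit normalization is applied across sensors, so
accelerometer distances in g and gyroscope distances in rad/s are
averaged on their raw scales. The test movelet takes the label of the
closest dictionary movelet.

**Vote.** The label at a timestamp is the modal matched label among the
movelet starting there and the following `vote_width - 1` (default: nine)
movelets. Because later movelets still overlap the timestamp, the vote
smooths isolated mismatches; its cost is a systematic early shift at
activity onsets, which is why momentary transitions are the
hardest class (their windows are quickly dominated by the following
posture).

## The three analysis modes

* `accel_only` — dictionary and test movelets from the accelerometer.
* `gyro_only` — dictionary and test movelets from the *original*
  gyroscope samples, not interpolated ones, mirroring how a
  gyroscope-only analysis would actually be run; the resulting labels
  (one per gyroscope timestamp) are then mapped to the accelerometer
  grid by taking the label of the closest gyroscope timestamp, so all
  modes are compared on one grid.
* `joint` — the gyroscope is linearly interpolated to the accelerometer
  timestamps (training and test alike) and 6-channel movelets are
  matched.

Linear interpolation is used because the signals are densely sampled
relative to body-movement bandwidth and the method's distance is
insensitive to sub-sample waveform detail; spline alternatives are
deliberately out of scope.

## Numerical and tie-break choices

These are all cases a correct implementation must decide and a prose
description of the method typically leaves open; the package fixes them
as follows, and its tests assert them.

* **Interval convention.** Annotations are half-open `[start, end)`, so
  adjacent intervals partition time with no double-labeled sample.
* **No extrapolation.** Interpolation never extends beyond the gyroscope's
  observed span; accelerometer samples without a bracketing gyroscope pair
  are dropped and counted (the counts travel on the joint stream and into
  run manifests). Fabricating angular velocity at the boundary would bias
  boundary movelets.
* **Argmin ties.** Smallest distance, then earliest activity in the
  dictionary's declared activity order, then lowest movelet index.
  Distances are computed as exact per-pair differences (not an
  inner-product expansion), so an identical pair scores exactly zero.
* **Vote ties.** Among modal labels, the one whose contributing movelet in
  the window has the smallest match distance; any remaining tie falls back
  to dictionary activity order.
* **Stream ends.** The last `vote_width - 1` movelet start times vote over
  the available (fewer) movelets rather than being dropped; the final
  `window_samples - 1` timestamps start no movelet and carry the `NA`
  unlabeled sentinel rather than an extrapolated label.
* **Nearest-timestamp mapping.** A target exactly midway between two
  source timestamps takes the earlier one's label.
* **Training truncation.** When a training bout exceeds the cap (default
  5 s), the *prefix* is kept — a deterministic, inspection-free choice.
* **Unlabeled samples** are carried as `NA` and excluded explicitly at
  evaluation, never silently dropped earlier; predictions of an excluded
  label against an included truth activity still count as errors in that
  truth column.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `nominal_hz` | 10 | Hz | canonical smartphone logging rate for this method |
| `window_samples` | 10 | samples | 1 s at 10 Hz: long enough to distinguish activities, short enough to avoid mixing two of them; specified in samples so non-10-Hz data works |
| `vote_width` | 10 | movelets | the movelet at `t` plus the subsequent nine |
| `train_seconds` | 5 | s | per-activity training cap; transitions are naturally shorter (~2 s) and used whole |
| `weights` | uniform `1/D` | — | equal-weight channel averaging; a weight vector is accepted so weighted fusion can be explored, but the tested default is uniform |

## The synthetic generator

`simulate_recording()` exists so every stage — IO, synchronization,
dictionaries, matching, voting, evaluation — is testable end to end
without any data download. It emulates the qualitative per-activity
signatures of phone-in-pocket sensing:

* **Stationary postures** are constant axis levels: standing
  `(−0.15, +0.98, 0.02)` g (phone vertical; gravity on y), sitting
  `(−0.73, 0.26, 0.64)` g (phone tilted in a pocket); the gyroscope is
  zero-mean for both — by construction the gyroscope cannot separate
  them.
* **Locomotion** (walk, stairs up/down) is sinusoidal per axis around an
  activity-specific baseline with distinct frequency (2.0, 1.6, 1.8 Hz),
  amplitudes and phases; walking's x/y accelerometer axes are out of
  phase, and the gyroscope axes are more synchronized than the
  accelerometer's.
* **Transitions** blend the two posture baselines with a smoothstep
  (`3u² − 2u³`) over the bout duration (default 2 s); the gyroscope
  carries a `sin²(πu)` arc that starts and ends at zero, with an extra
  damped early oscillation for stand-to-sit, which begins more variably
  than sit-to-stand.
* **Noise** is i.i.d. Gaussian per sample and channel, default 0.02 g /
  0.02 rad/s — small against the signal separations, so classification
  is solvable but not degenerate.
* The gyroscope timestamp grid is shifted by `gyro_offset` (default
  0.03 s) from the accelerometer's, reproducing the unsynchronized-sensor
  situation that motivates interpolation.

A second model set, `models_with_shared_accel()`, gives walk and stairUp
identical accelerometer parameters while keeping their gyroscopes
distinct — the mirror image of the sit/stand situation, used to probe
fusion from the accelerometer-blind side.

**What passing tests do and do not show.** The generator produces
stationary sinusoids and exact baselines; real locomotion has cycle
irregularity, drift, orientation changes and heavy-tailed artifacts. A
pipeline that is correct and effective on these signals is demonstrably
implementing the method (the properties tested — metric identities,
oracle agreement, self-classification, the two fusion directions — are
properties of the algorithm, not the waveform), but the resulting
accuracy figures say nothing quantitative about accuracy on real phone
recordings.

## Problem sizes used in tests and the acceptance script

Default study conditions throughout: 10 Hz, 7 activities, 5-s training
bouts (2 s for transitions, used whole), a test schedule of ~58 s
(nine bouts, 569–571 evaluated timestamps per mode), dictionaries of 225
movelets (41 × 5 + 11 × 2). Metric and classifier oracle checks use 1000
and 100 randomized instances respectively. At these sizes the whole
suite and the acceptance script each run in well under a minute on a
laptop-class core.

## Known limitations

* Transition accuracy is intrinsically low (~45–50% here): the vote
  window leaks the following posture into momentary activities. This is
  a property of the method, visible in its original setting too, not an
  implementation artifact.
* The gyroscope-only mode's sit/stand split is decided by noise, so its
  stationary accuracy (and the stand-as-sit percentage) fluctuates
  around 50% across seeds; only its direction relative to the joint mode
  is stable.
* Activities outside the dictionary can only ever be misclassified;
  evaluation supports excluding such truth labels explicitly.
* No time-warping of movelets, no per-channel weighting in the tested
  default, no cubic/B-spline interpolation — all deliberate scope
  boundaries.
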