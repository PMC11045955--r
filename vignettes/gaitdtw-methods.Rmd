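---
title: "Methods: swing-phase mode recognition by voting mDTW"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: swing-phase mode recognition by voting mDTW}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The recognition problem

`gaitdtw` classifies individual gait cycles of lower-limb sensor data into
three locomotive states: steady level walking (LW) and the two swing-phase
transitions, level walking to stair climbing (LW_SC) and level walking to
stair descending (LW_SD). The design constraint that shapes everything
else is *timing*: a prosthesis or exoskeleton controller needs the label
before the stance phase begins, which in a toe-off-anchored cycle is
roughly the first 40 %. Cycles therefore start at toe-off (swing first),
and the classifier operates on a *prefix* of the cycle — the samples
accumulated since toe-off — rather than on complete strides.

## Pipeline and assumptions

1. **Filtering.** Each channel is low-pass filtered with a second-order
   Butterworth filter, 15 Hz cutoff, applied forward and backward
   (zero phase). Zero-phase filtering is appropriate because processing is
   per-recorded-cycle, not causal streaming; it doubles the attenuation in
   dB (the magnitude response is squared) and leaves gait-band content
   (< 10 Hz) untouched. Ends are padded by odd reflection over roughly
   three cutoff periods so the filter's zero-state start-up transient
   decays inside the padding; without this, constants are visibly bent at
   the edges.
2. **Normalization.** Channels are z-scored per recording (the offline
   convention for normalizing whole recorded signals). Queries and
   templates therefore live in the same space by construction, and
   amplitude scaling commutes with the z-score, which is why amplitude
   augmentation interacts cleanly with normalization. Prefixes are cut
   *after* normalization: z-scoring a partial cycle on its own statistics
   would bias early-recognition comparisons. Template sets additionally
   store their training cycles' per-channel statistics as metadata, so an
   external query stream can be placed into a template set's space with
   `normalize_signal(x, params)`. FSR (pressure) channels are exempt from
   normalization by default because the toe-off detector thresholds their
   physical 0–1 scale.
3. **Thigh angle.** The sagittal segment tilt is extracted from IMU data
   in two stages: accelerometer inclination (`atan2(a_x, a_z)`, degrees)
   fused with the integrated gyroscope rate by a complementary filter
   (weight `alpha = 0.98` on the gyro path), then smoothed by a linear
   Kalman filter with state `[angle, gyro_bias]`, gyro-driven prediction
   and the complementary angle as the measurement. The hand-off between
   the two filters is a design interpretation — the pipeline is stated in
   the literature only as "complementary filter and Kalman filter" — and
   we chose complementary-angle-as-measurement because it keeps the Kalman
   measurement noise roughly white. Noise parameters (`q_angle = 0.002`,
   `q_bias = 5e-4`, `r_angle = 1`, all per-step, degrees) were tuned once
   on the synthetic generator so that the fused estimate beats both the
   accelerometer-only and the gyro-only estimate on a known trajectory
   with noisy accelerometer and biased gyro; they are exposed as
   arguments.
4. **Segmentation.** Toe-off is detected from the in-shoe FSRs: after a
   stance interval (both heel and ball loaded above threshold +
   hysteresis), the first sample with both below `fsr_low_threshold`
   (default 0.05 normalized pressure, hysteresis 0.02) is the candidate,
   refined to the nearest local extremum of the instrumented shank
   accelerometer z axis within ±50 ms. Candidates closer than
   `min_cycle_duration` (0.6 s) to the previous toe-off are rejected;
   segmented cycles outside [0.6 s, 2.5 s] are dropped, standing in for
   manual curation. The FSR-plus-accelerometer rule is our own
   concretization — the physical signature of toe-off is forefoot
   unloading, and the accelerometer burst pins the sample — with every
   constant configurable. Cycle labels come from the label interval
   containing the cycle midpoint (majority-overlap labeling is available).
5. **Augmentation.** Transition cycles are rare (tens against thousands of
   LW cycles in a typical protocol), so each one is expanded 13-fold:
   amplitude scaling by 96/98/102/104 %, resampling by the same four
   ratios, and additive white Gaussian noise at 30/35/40/45 dB SNR. The
   resampling ratios are not prescribed anywhere, so the amplitude ratios
   are reused — symmetric few-percent perturbations of cycle length, the
   second axis along which gait naturally varies. Augmentation runs after
   filtering and before normalization by default. Derived cycles carry
   provenance (`derived_from`, operation, parameter) and inherit subject
   and label; they are **never** used for template building by default and
   never cross subject boundaries, so fold hygiene is auditable
   (`audit_loso()`).
6. **Templates.** For each subject and mode, cycles are linearly resampled
   to `L = round(mean(length))` and averaged sample by sample. The mean
   length is computed per mode (templates of different modes may differ in
   `L`); rounding to nearest is our choice where "average length" leaves
   it open. Elementwise mean is the default, with a median option for
   outlier-heavy data. No DTW-barycenter averaging: plain
   resample-and-average is the method under study.
7. **Classification.** The mDTW distance is computed between the query
   prefix and each mode template truncated to the *same fraction*. We
   truncate the template rather than matching a partial query against a
   full template because the latter forces the tail of the template to be
   absorbed as spurious warping cost; an open-end variant (free template
   endpoint, minimum over template prefix lengths) is available behind
   `open_end = TRUE` for comparison. Each subject's template set votes for
   its arg-min mode; the final label is the plurality vote, with ties
   broken by the smallest mean distance across all voters (and flagged).
   Arg-min ties inside a set are broken by the fixed mode order LW, LW_SC,
   LW_SD — deterministic and recorded.

## The DTW core

The pointwise cost is the vector Euclidean distance over channels; the
cumulative matrix follows the standard three-predecessor recurrence with
prefix-sum boundary conditions, and the distance is the raw `C[m, n]` —
no path-length normalization, because distances are only ever compared
between equal-status templates at the same prefix fraction. Backtracking
prefers diagonal, then vertical, then horizontal on ties, which favors
short paths and is deterministic. No warping window is applied by default
(none is part of the method); a Sakoe–Chiba band is available for speed.

The default multichannel strategy is **dependent** (one shared warping
path over vector-valued samples). The alternative — independent
per-channel DTW with summed distances — is implemented and switchable,
because the method description ("takes all dimensions into account when
finding the optimal match") is most naturally read as a shared path but
does not strictly exclude the per-channel reading. On one channel both
reduce exactly to scalar DTW, which the tests pin down.

The dynamic program is implemented in C++ (via Rcpp) with two rolling
rows for the distance-only hot path; matrices and paths are materialized
only on request. The test suite verifies the DP against an *exhaustive
enumeration of all monotone warping paths* — plain recursion, no
memoization — on every pair of ternary sequences up to length 4
(14 400 pairs) plus sampled length-5 pairs.

One textbook-looking invariant is deliberately **not** asserted:
"appending a sample pair with positive pointwise distance never decreases
the distance". It is false — appending can open a cheaper alignment for
the old suffix (e.g. `x = [0], y = [0, 5]` has distance 5, while
`x' = [0, 5], y' = [0, 5, 4]` has distance 1). What is true, and tested,
is that the appended pair's own cost is a lower bound on the new
distance.

## The synthetic generator

The generator exists because the kind of multi-subject gait corpus this
method is built for is not publicly deposited; it produces data with the
same *structure* and known truth, not the same morphology.

Per-mode, per-channel prototypes are sums of at most six harmonics of the
cycle phase: a channel-specific base shape shared by all modes plus two
fixed "transition shapes" added with per-channel weights for LW_SC and
LW_SD. The shapes are chosen so the three modes differ from the very start
of the cycle — the premise that makes swing-phase recognition possible at
all, and one that real stair transitions satisfy (hip and thigh
trajectories diverge early in swing). Subjects perturb prototypes by a
per-channel lognormal amplitude factor (sdlog 0.1) and a common Gaussian
phase shift (sd 2 samples) — the two variation axes that the
scaling/resampling augmentation scheme presumes matter. Cycle durations
are Gaussian (1.1 ± 0.05 s at 100 Hz; stance onset at 40 % of the cycle),
the default corpus is 9 subjects × 30 cycles with a 10 %/10 % transition
share (deterministic counts, shuffled order, at least one per mode), and
sensor noise is white Gaussian at 35 dB SNR, the midpoint of the
augmentation SNR ladder. The sampling rate (nowhere stated for the
original hardware) defaults to 100 Hz and is carried explicitly by every
container. FSR channels follow a stance-plateau/swing-zero pattern whose
fall reaches zero exactly at the next true toe-off, and the shank accel-z
carries an in-phase harmonic burst peaked at toe-off, so the detector can
be scored against truth (±2 samples at ≥ 30 dB SNR).

What the generator does *not* emulate: real signal morphology (no
biomechanical simulation), within-subject drift, label noise from manual
video annotation, sensor dropout, and cross-mode timing differences
(transition cycles are not systematically longer). Perfect accuracy on
the synthetic benchmark therefore demonstrates the pipeline's
correctness under its stated assumptions — separable, quasi-periodic
prototypes — not field performance on recorded gait.

## Evaluation choices

- "Overall accuracy" is pooled (micro) accuracy over all evaluated
  cycles; F1 is macro-averaged over the three classes. With a ~10:1:1
  class ratio a weighted F1 would collapse onto accuracy; macro keeps the
  transitions visible.
- LOSO builds each voting pool from all *other* subjects' original
  cycles; the held-out subject's cycles — augmented copies included — are
  what gets scored. Every report carries a provenance audit trail
  (`audit_loso()` re-derives fold hygiene from cycle ids).
- Forward selection is greedy on pooled LOSO accuracy with a
  strict-improvement stopping rule; ties stop. A `"degradation"` rule
  (stop only when accuracy would drop) is also provided, because reported
  selection traces elsewhere show a final *drop* when one channel too
  many is added, which is consistent with either reading of "did not
  improve".
- The personalization comparison splits one subject's originals in half
  per mode (first halves → personalized templates, second halves →
  evaluation) and contrasts that with the user-independent voting pool on
  the same evaluation halves.

## Problem sizes and tolerances in the test suite

Tests run on deliberately small corpora chosen as the smallest sizes at
which each property is stable: 3–4 subjects × 12–18 cycles for behavioral
checks, 9 subjects × 12 cycles for the noiseless-exactness and
prefix-monotonicity properties, exhaustive DTW verification up to length
4 with sampled length-5 pairs. Monte-Carlo assertions (template
convergence at the σ/√N rate, SNR attainment within 0.5 dB,
prefix-accuracy monotonicity within 2 percentage points) use fixed seeds
and tolerances stated inline. Degenerate inputs have defined behavior
throughout: constant signals refuse to z-score, zero-power channels
refuse SNR-scaled noise, prefixes shorter than 4 samples refuse to warp,
template sets refuse subjects missing a mode (naming it), and empty
cycle/fraction lists yield empty results rather than errors.

## Known limitations

- Three states only; steady stair modes, sit/stand and other transitions
  are out of scope by design.
- The unit of classification is a (partial) cycle delivered by
  segmentation; there is no streaming sample-by-sample controller.
- Dependent mDTW assumes channels share one time axis; strongly
  desynchronized channels would favor the independent strategy.
- Template averaging assumes roughly unimodal per-mode gait; multimodal
  users (e.g. changing gait strategies) would need multiple templates per
  mode, which the voting architecture could host but does not currently
  implement.
- Runtime grows linearly in voters × modes and quadratically in prefix
  length; the C++ core handles desk-scale corpora comfortably, but no
  lower-bounding or pruning is implemented.
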