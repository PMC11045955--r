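# gaitdtw

Swing-phase recognition of locomotion modes and mode transitions from
wearable gait sensors, by multidimensional dynamic time warping (mDTW)
template matching with majority voting.

## The problem

A powered lower-limb prosthesis must know, early in the swing phase, which
kind of step its user has just begun — steady level walking (LW), a
walking-to-stair-climb transition (LW-SC), or a walking-to-stair-descend
transition (LW-SD) — so that the joint controller can switch to the right
mode before the power-demanding stance phase starts. `gaitdtw` implements a
lightweight template-matching recognizer for this setting: gait cycles are
segmented at **toe-off** (swing phase first, inverting the usual
heel-strike convention), and the signals accumulated since toe-off are
compared against per-subject reference templates.

## The method

Two sequences `X = x_1..x_m` and `Y = y_1..y_n` (channels × samples) are
aligned by dynamic time warping. The pointwise cost matrix
`D[i,j] = ||x_i − y_j||` (vector Euclidean norm over channels) feeds the
dynamic program

```
C[i,j] = D[i,j] + min(C[i−1,j], C[i,j−1], C[i−1,j−1])
```

with `C[1,1] = D[1,1]` and prefix-sum boundaries; `C[m,n]` is the mDTW
distance and backtracking recovers the optimal warping path. The default
"dependent" strategy warps all channels on one shared path; an
"independent" per-channel variant is available for ablation.

Around this core the package provides:

- **Preprocessing** — zero-phase 2nd-order Butterworth low-pass (15 Hz),
  z-score normalization, and complementary + Kalman filter fusion of IMU
  accelerometer/gyroscope data into a sagittal segment-tilt angle.
- **Segmentation** — toe-off detection from in-shoe pressure (FSR)
  unloading refined by the shank accelerometer, then toe-off-to-toe-off
  cycle slicing with mode labels.
- **Augmentation** — minority (transition) classes expanded 13× by
  amplitude scaling (96–104 %), resampling, and additive white Gaussian
  noise at 30–45 dB SNR.
- **Templates** — per subject and mode, cycles are resampled to the
  average cycle length and averaged sample by sample.
- **Classification** — an unknown (possibly partial) cycle is compared,
  prefix against prefix, with every subject's template set; each set votes
  for its nearest mode and ties are broken by the smallest mean distance
  across voters.
- **Evaluation** — leave-one-subject-out (LOSO) cross-validation, pooled
  accuracy and macro-F1, prefix-fraction sweeps (early recognition),
  greedy forward channel selection, and personalized-vs-user-independent
  comparison.
- **Synthetic generator** — multi-subject, multichannel quasi-periodic
  gait recordings with harmonic mode prototypes, subject effects, sensor
  noise, and exact ground truth, so the whole pipeline is testable without
  recorded data.

## Worked example

```r
library(gaitdtw)

spec   <- generator_spec(n_subjects = 5, n_cycles = 20, seed = 42)
corpus <- make_benchmark(spec)
corpus
#> <gait_benchmark> 100 cycles, 5 subjects; modes: LW=80 LW_SC=10 LW_SD=10

fit <- mdtw_classifier(corpus$cycles, channels = spec$channels[1:8])
fit
#> Voting mDTW locomotion-mode classifier
#>   voters (template sets): 5
#>   channels: 8 - instr_hip.joint_angle, uninstr_hip.joint_angle, ...
#>   strategy: dependent

# user-independent prediction from the first 30% of one cycle
q <- corpus$cycles[[3]]
predict(fit, q, prefix_fraction = 0.3, exclude_subject = q$subject_id,
        details = TRUE)[[1]]
#> <gait_prediction> LW (prefix 30%, 4 voters)

# leave-one-subject-out at 30% of the gait cycle
loso_evaluate(corpus$cycles, channels = spec$channels[1:8],
              prefix_fraction = 0.3)
#> LOSO evaluation @ 30% of gait cycle: accuracy 100.00%, macro F1 1.0000
#> Pooled confusion matrix (rows = truth):
#>         LW LW_SC LW_SD
#>   LW    80     0     0
#>   LW_SC  0    10     0
#>   LW_SD  0     0    10
```

The accuracy is the pooled fraction of correctly labeled cycles across all
held-out subjects; macro F1 averages the per-class F1 so the rare
transition classes are not swamped by level walking. On this synthetic
benchmark the three mode prototypes separate from the first 10 % of the
cycle, so recognition is already perfect at a 30 % prefix — mirroring the
regime the method is designed for, where a decision well before stance
(≈ 40 % of a toe-off-anchored cycle) is what matters.

A command-line front end over the same functions is installed at
`system.file("cli/gaitdtw.R", package = "gaitdtw")` with subcommands
`simulate`, `segment`, `augment`, `templates`, `classify`, `evaluate` and
`select-channels`.

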