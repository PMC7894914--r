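---
title: "Classifying lifting risk from wearable IMU signals: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying lifting risk from wearable IMU signals: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liftrisk)
```

## The problem

Occupational back injury is strongly associated with *where* a lift
originates relative to the body. The ACGIH threshold-limit-value scheme
divides the sagittal plane into 12 zones; collapsing them with the Los
Alamos-derived simplification gives three relative risk levels — zones 4-5
are **low** risk, 6-9 **medium**, and 1-3 with 10-12 **high** — so a
balanced 12-zone protocol yields a deliberately imbalanced 1:2:3 class
ratio. `liftrisk` implements a pipeline that classifies a single lifting
trial into one of these levels from six body-worn inertial measurement
units (upper back at T12, both wrists, dominant upper arm, waist, dominant
thigh), each providing a tri-axial accelerometer and gyroscope at 25 Hz —
36 signal channels per frame.

The scientific difficulty is the data regime: specialised lifting protocols
produce hundreds, not millions, of trials (the motivating protocol has 720:
10 subjects x 12 zones x 6 lifts), the activities are visually similar, and
the classes are imbalanced. The package's core is a compact
convolutional-network approach tailored to this regime, together with the
evaluation machinery such small imbalanced problems need.

## Preprocessing and the image encoding

The pipeline order is fixed: **filter → pad → scale → encode**.

* **Band-pass filter.** Every channel is filtered independently with a
  Butterworth band-pass built from an order-2 low-pass prototype, passband
  2-12 Hz at 25 Hz sampling. This removes gravity/orientation drift (DC)
  and high-frequency sensor noise while keeping the voluntary-movement
  band. Filtering is zero-phase (forward-backward) by default so that the
  group delay does not shift burst positions; a causal single pass is
  available for streaming use. The band-pass is realised by `signal::butter`
  / `signal::filtfilt`; with the upper edge at 12 Hz against a 12.5 Hz
  Nyquist the design is near the edge of stability, and the package's tests
  pin the realised steady-state gain to the analytic prototype response at
  interior passband frequencies within 2%.
* **Padding.** Trials are at most 30 s (750 frames); most last 10-15 s.
  Each frames x 36 matrix is rearranged into a 12 x 750 x 3 tensor (12
  sensor streams, placement-major with accelerometer before gyroscope;
  frames; x/y/z axes) and zero-extended to 750 frames. `pad_start` records
  where padding begins; trials longer than the window raise an error rather
  than being silently truncated.
* **Scaling.** An affine transform per axis-channel (36 of them) is fitted
  on the *training fold only* and applied unchanged to the test fold.
  The default is z-scoring (mean 0, SD 1 per channel); min-max scaling to
  [-1, 1] is available. Channel statistics are computed over all tensor
  cells including the pad region, and pad cells are reset to exactly 0
  after scaling, so padding sits at the neutral value of the z-scored
  scale. Held-out data may legitimately fall outside the nominal bounds.
* **Encoding.** Each axis-channel's 12 x 750 slice is flattened time-major
  (all 12 streams at frame 1, then frame 2, ...) and the 9,000 values are
  wrapped row-by-row into a 95 x 95 grid; the final 25 cells per channel
  are padding. 12 x 750 x 3 = 27,000 features; 3 x (95 x 95 - 25) = 27,000.
  Row-major wrapping of a time-major flattening keeps temporally adjacent
  samples spatially close within image rows, which is the property the
  convolutional model exploits. The encoding is a bijection
  (`decode_image()` inverts it exactly), which also means per-channel
  scaling commutes with encoding; the package scales in the tensor domain
  where "per sensor channel" is well defined.

Two readings of the published pipeline were genuinely open. Whether
standardisation happens before or after image formation is immaterial
because the encoding is value-preserving; we scale before encoding and
document that equivalence. Whether "each sensor" means 12 streams or 36
axis-channels we resolve to 36 axis-channels, the finer and more common
convention.

## The models

The proposed classifier is a VGG-B-flavoured network shrunk for small
data, with **average pooling** in place of max pooling:

| stage | layers |
|---|---|
| block 1 | conv 32@3x3 (ReLU) → avg-pool 2x2 → dropout 25% |
| block 2 | conv 64@3x3, conv 64@3x3 → avg-pool 2x2 → dropout 25% |
| block 3 | conv 128@3x3, conv 128@3x3 → avg-pool 2x2 → dropout 25% |
| head | flatten (11x11x128 = 15,488) → dense 1024 (ReLU) → batch-norm → dropout 25% → softmax 3 |

Convolutions are size-preserving (VGG convention), so pooling alone
downsamples: 95 → 47 → 23 → 11 by floor division. Average pooling keeps
information from all four cells of each pool, which matters for
low-sample-rate oscillatory signals where max pooling would clip
fluctuations. Four comparison models are built from the same engine: the
identical max-pooling variant, a pooling-free simple CNN (32/64/128
convolutions straight into softmax), an MLP (flatten → dense 1024 →
dropout → softmax), and a convolutional-LSTM (`cnn_lstm`) that treats the
12 x 750 x 3 tensor as a 750-step sequence of 36 features — 1-D
convolutions over time followed by LSTM layers, in the DeepConvLSTM
family. Where the comparison architectures were not fully pinned down, the
defaults (4 conv layers with 64 filters and kernel 5; 2 LSTM layers of 128
units; MLP width 1024) follow the cited architecture families and are all
configurable.

The network engine itself — im2col+GEMM convolutions, pooling, batch
normalisation, dropout, LSTM backpropagation through time, softmax
cross-entropy, ADAM, and input-gradient computation — is implemented in
the package with RcppArmadillo, and every layer's analytic gradient is
verified against central finite differences in the test suite.

### Training protocol

All models train identically: minibatch ADAM (standard moments
$\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$) on categorical
cross-entropy, with an L2 penalty $\lambda \lVert W \rVert^2$ applied
solely to the final softmax layer's kernel. The selected hyperparameters
are $\lambda = 10^{-5}$, learning rate $\alpha = 10^{-3}$ and dropout 25%;
`hyperparameter_sweep()` re-derives such choices by cross-validated $R_K$,
reporting accuracy alongside because the two can rank settings
differently.

Early stopping monitors the **training** cross-entropy at the end of each
epoch (no validation split is carved out of the training fold — worth
stating prominently because it differs from common practice), with
min-delta 0 and patience 10; on stopping, the weights of the minimum-loss
epoch are restored. A non-finite loss aborts with a diagnostic naming the
learning rate, since that is the signature of the unstable-$\alpha$
regime. Batch size (32) and the epoch cap (500) are unconstrained by the
protocol and configurable.

Two numerical choices deserve a note. Batch-norm running statistics use
momentum 0.9 rather than the framework-default 0.99: with a few hundred
minibatch updates (small data, early stopping) a 0.99 momentum leaves the
inference statistics dominated by their initialisation, visibly degrading
held-out accuracy while training accuracy is high. And predicted-class
ties break toward the higher risk level — the conservative direction for a
safety application.

## Evaluation

Per-zone stratified Monte-Carlo cross-validation: each of the 4 folds
samples, *within every zone*, 25% of that zone's trials into the test side
(largest-remainder rounding, so 60-trial zones split 45/15 and the global
75/25 is hit exactly). Sampling within zones makes a zone absent from
either side structurally impossible — the failure mode that plain random
subsampling of 60-trial zones would hit. The folds are independent random
draws, not a disjoint partition: four folds each holding out 25% with
per-zone quotas cannot be a partition with these guarantees, so the
Monte-Carlo reading is the consistent one. Splitting is by trial to match
the protocol being emulated; subject-wise splitting is available
(`by_subject = TRUE`) for generalisation studies but is not the default.

Fold results are reported per fold and pooled. Pooling averages the four
confusion matrices and rounds back to one test-set size (largest
remainder), so the pooled matrix reads like a single 180-trial test; the
per-fold matrices are retained since rounding loses information, and both
fold-mean and pooled-matrix summary statistics are emitted.

From a confusion matrix $C$ (actual rows, predicted columns) the package
computes per-class precision $TP/(TP+FP)$, recall $TP/(TP+FN)$, their
harmonic-mean F-measure, overall accuracy, and the Gorodkin $R_K$
correlation

$$R_K = \frac{c\,s - \sum_k t_k p_k}
{\sqrt{s^2 - \sum_k p_k^2}\,\sqrt{s^2 - \sum_k t_k^2}}$$

with $c$ the trace, $s$ the total, $t_k$/$p_k$ the actual/predicted class
totals. $R_K$ generalises the Matthews correlation to many classes, lies
in $[-1, 1]$, and 0.7 is conventionally the threshold of satisfactory
agreement; the suite checks it against the binary MCC exhaustively on
small 2x2 matrices. Degenerate matrices (a single observed or predicted
class) return 0 with a warning, and zero-denominator precision/recall are
reported as 0 with a warning; display rounding is 3 decimals while
internal values stay at full precision.

## Saliency

For a trained model and class $c$, the saliency map is the elementwise
magnitude of $\partial S_c / \partial I$ at the input itself — the
first-order answer to "how much would each input element, if perturbed,
move the class score". $S_c$ is the pre-softmax logit by default (the
post-softmax probability saturates and shrinks gradients; both are
available). Image-model maps reduce the three axis channels by max of
absolute values (sum available); sequence-model maps are 36 channels x 750
frames. Class-average maps aggregate over the trials whose *true* class is
$c$. `sensor_importance()` sums a sequence map over each placement's six
rows, so placement importances conserve total map mass, and
`saliency_frame_profile()` collapses either map type to one weight per
frame (image maps are first decoded back to the tensor layout through the
encoding bijection).

## The synthetic-lift generator

The package is exercised end-to-end on simulated trials, because the
original recordings are not distributed with it. The generator emulates
the study conditions: 10 subjects x 12 zones x 6 trials at 25 Hz by
default, durations uniform on 10-15 s within a 30 s window. Each trial is
white sensor noise plus two Gaussian-windowed oscillatory bursts — an
object-pickup burst near 18% of the trial and a return-to-upright burst
near 82% — with carriers at 4.5 and 5.5 Hz (inside the passband) and a
0.5 s envelope SD. Burst amplitude across placements encodes the class:
back and wrist channels scale fully with `class_separation` x (class - 1),
the other placements at a quarter rate, so the class signal concentrates
where the real phenomenon concentrates it. `class_separation = 0` makes
the classes exchangeable (verified by a location test on channel
energies); large separation with zero noise makes them nearest-centroid
separable (verified by brute force). Burst centres and widths are recorded
per trial, giving saliency tests an assertable ground truth.

What the simulator does *not* emulate: biomechanically realistic
kinematics, inter-subject anthropometric variation, within-class zone
differences, or correlated sensor noise. Passing tests therefore
demonstrate that the pipeline recovers a class-dependent burst structure
it is pointed at — not that it would reach any particular accuracy on real
recordings.

## Problem sizes used by the tests

The acceptance-style checks train the proposed model on a scaled-down easy
regime chosen once: 5 subjects x 12 zones x 3 trials (180 trials),
`class_separation = 6`, `noise_sd = 0.05`, 4 stratified folds, batch 16,
a 12-epoch cap. The image-saliency localisation checks reuse a smaller
2 x 12 x 2 set of fixed 12 s lifts. The sequence-model checks use
4 subjects x 12 zones x 3 trials of fixed 5 s duration padded to a
150-frame window, with a reduced `cnn_lstm` (16 filters, 2 convolutions,
one 32-unit LSTM): on zero-padded input the last-step LSTM readout decays
the cell state through every padding step (forget-gate activation < 1), so
hundreds of trailing pad frames erase the burst information before it is
read out — the short window keeps the scaled test about the architecture
rather than about that degeneracy, and variable trial lengths would
additionally confound amplitude with pad length at this training size.
These sizes are the package's own choice of a small, well-separated
benchmark on which the full-size proposed architecture should be
essentially perfect; the published-scale protocol (720 trials, full early
stopping, 750-frame sequences) is available through the same
`experiment_config()` interface.

## Known limitations

* The engine is single-threaded CPU code; it is sized for hundreds of
  trials, not ImageNet-scale work, which is exactly its design point.
* Early stopping on training loss can under-regularise relative to
  validation-based stopping; the design follows the protocol being
  implemented and is flagged above.
* Automatic lift start/end segmentation of longer recordings is out of
  scope; trials are assumed pre-trimmed.
* A scalar continuous risk score (as opposed to the 3-way softmax) is not
  derivable from the classifier and is not implemented.
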