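---
title: "Methods: instantaneous HD-sEMG gesture recognition with multi-stream adaptive batch normalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: instantaneous HD-sEMG gesture recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model, the algorithms and
the design decisions behind them. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. From electrode grids to images

High-density surface EMG records muscle activity on a 2-D electrode array —
8 × 16 for the CapgMyo armband, 7 × 24 for CSL-HDEMG-style montages, and a
degenerate 1 × 10 "grid" for sparse electrode sets. A `grid_layout` is a
bijection from channel index to grid position. The instantaneous frame (all
channels at one sampling instant) becomes a grayscale image by the clipped
linear map `pixel = 255 * clip((value - lo)/(hi - lo), 0, 1)`
(`frame_to_image()`).

**Input range.** CapgMyo-style signals are normalized amplitudes in
[−1, 1]; the package maps that full range to [0, 255] by default
(`in_range = c(-1, 1)`), preserving sign information. Because the first
network layer is a normalization layer, any affine choice of `in_range` is
absorbed; the option exists mainly for data already rectified to [0, 1].
Intensities are kept as real numbers — quantization to 8 bits would only
discard information before the network input.

**Conditioning.** Power-line interference is removed by a 45–55 Hz
second-order Butterworth band-stop (`bandstop_filter()`, via the `signal`
package). Filtering is zero-phase (forward–backward) so per-frame labels
stay aligned with the signal; the effective order doubles, which is
accepted. A 3 × 3 spatial median filter (`spatial_median_filter()`) is
available for noisier montages; neighborhoods are truncated at image
borders, i.e. border pixels take the median of their available neighbors —
the alternative (padding) would bias border medians toward the pad value.

**Record I/O.** Records follow the CapgMyo per-trial layout: fields `data`
(frames × channels), `gesture`, `subject`, `trial`, with 1000-frame
preprocessed trials. The package's native container serializes exactly
these field names (RDS of a named list); the container dialect is
deliberately thin so adapters for other matrix formats can wrap
`session_record()` directly. `segment_middle_window()` keeps the middle
one-second (1000-frame) window of every contiguous non-rest segment — the
static hold phase — dropping the extra frame at the segment end when the
leftover is odd (`floor((L-W)/2)` leading frames skipped), a deterministic
choice within half a frame of exact centering. Rest-vs-gesture segmentation
trusts the per-frame labels (0 = rest); no onset detection is attempted
because frames are labeled by the guiding stimulus, and transition frames
carry the upcoming gesture's label.

## 2. The classifier

The network (`emgnet_spec()`, `build_network()`) has eight layers: two 3 × 3
convolutions (64 filters, stride 1, padding 1), two locally connected layers
(64 per-position 1 × 1 filters with untied weights — implemented as an
independent dense 64→64 map at every grid position, which is what "locally
connected, non-overlapping 1 × 1" means once weights are untied), then fully
connected layers of 512, 512 and 128 units, and a G-way softmax. ReLU
follows every hidden layer; batch normalization is applied to the input and
before every ReLU; dropout 0.5 follows layers 4, 5 and 6. Weights use
He (fan-in) initialization; normalization statistics start at mean 0,
variance 1.

Site conventions the reference description leaves open, fixed here:

* the input site uses a *single* statistic over all pixels (the feature
  dimension of an image input is 1);
* convolutional and locally connected sites keep per-channel statistics
  pooled over batch and positions; fully connected sites are per-unit;
* the input site carries learnable scale/shift like every other site, for
  uniformity;
* the variance estimator is the population (biased) estimator over the
  block, with an epsilon guard of 1e-5 inside the square root;
* layer biases are kept everywhere (they are redundant under normalization
  for the convolutional sites but harmless, and the parameter count is
  verified against a closed form in the tests).

Training (`emgnet()`, `emgnet_schedule()`) is plain SGD: reference schedule
batch 1000, 28 epochs, weight decay 1e-4 (applied to weight matrices, not
biases or scale/shift), learning rate 0.1 divided by 10 after epochs 16 and
24. Dropout is active only in training mode.

## 3. Multi-stream normalization and adaptation

Each recording session is one source domain. In a training batch of m
frames, rows are grouped into M session-homogeneous blocks of P = m/M
frames; every normalization site standardizes block k with that block's own
moments and applies the shared scale/shift (`multistream_train_pass()`).
With M = 1 this is exactly classical batch normalization — an equality the
tests assert to float tolerance. Batches are rebuilt randomly every epoch;
when fewer sessions than M exist, sessions are reused within a batch rather
than shrinking M, keeping the statistic cardinality fixed. Per-stream
running moments are maintained by moving average (momentum 0.1) during
training.

**Prediction before any adaptation** needs a single statistic set; the
package pools the M stream statistics by the law of total variance (mean of
stream means; mean of stream variances plus the between-stream variance of
the means). This is the least-arbitrary "no adaptation" baseline and is the
state `adapt()` starts from.

**Adaptation (`adapt()`)** re-estimates the statistics from unlabeled
target-session frames with all weights frozen (the tests assert the weight
fingerprint is unchanged). Sites update bottom-to-top: each site's moments
are computed from activations normalized by the *already updated* lower
sites, implemented as successive forward passes truncated at each site.
Within one call, all calibration batches contribute with equal per-frame
weight, so the first site's statistics equal the pooled calibration moments
exactly and the result is invariant to how frames were batched — an
important property in practice, because calibration data arrive ordered by
gesture, and an exponentially weighted pass would bias the statistics
toward whichever gestures came last. Across calls the accumulation
continues (never-ending use), with an optional exponential mode
(`momentum` in (0, 1]) when recent data should dominate. Dropout stays off
during adaptation; the weights' path must be deterministic.

**Fine-tuning (`finetune()`)** is the supervised follow-up when labeled
calibration data exist: ordinary SGD on the target session (a single
stream), updating the adapted statistics by moving average as it goes. The
package does not re-run unsupervised adaptation after fine-tuning.

## 4. Inference and evaluation

Per-frame prediction takes the argmax of the softmax (ties toward the
smallest label, deterministically). Majority voting over a sliding window
(stride one frame) trades latency for accuracy: `majority_vote()` returns
the modal label, ties again toward the smallest label. `evaluate()` reports
per-frame accuracy, voted accuracy at requested window sizes, a confusion
matrix and a per-unit breakdown. Windows never straddle trial boundaries; a
window longer than a trial degenerates to one whole-trial vote; voted
accuracy averages over all window positions of all test trials (not over
trials), and a window's reference label is the majority of its true frame
labels. Voting uses argmax labels, not averaged probabilities — it counts
votes.

Protocols (`make_protocol()`): intra-session (odd trials train / even
trials test, the 50/50 split), inter-session (leave-one-session-out per
subject) and inter-subject (leave-one-subject-out). Calibration defaults to
the unlabeled test-session data. Trial numbering is 1-based.

## 5. The synthetic generator

`generator_config()` describes a session-structured database:

* per-gesture activation maps: Gaussian-smoothed noise fields on the grid,
  rescaled to [0, amplitude] (default 0.6 so that gain distortions rarely
  clip at ±1), resampled until all pairwise correlations are below 0.9;
  patterns are shared across subjects so that inter-subject transfer has
  signal, while all subject/session individuality comes from distortions;
* trials: a raised-cosine envelope ramps the pattern up over `ramp_frames`,
  holds for `frames_per_trial`, ramps down; trials are separated by rest
  frames (label 0); the middle-window segmentation recovers exactly the
  hold phase, mimicking the static-movement convention;
* noise: i.i.d. Gaussian per channel (`noise_sd`, default 0.1) plus a
  common-mode 50 Hz sinusoid (`powerline_amp`, default 0.05) that
  `bandstop_filter()` demonstrably removes;
* session shift (`shift_params()`): a circular displacement of the
  activation pattern drawn per session (default up to ±1 column — the
  column axis wraps because the physical array is a ring of modules around
  the forearm; the row axis does not shift by default), per-channel gains
  `exp(N(0, 0.2))` and offsets `N(0, 0.05)`. All draws are keyed
  deterministically by (master seed, subject, session), so any experiment
  is exactly reproducible.

What the generator emulates is the *statistical* structure of inter-session
variability — covariate shift keyed to session identity — not muscle
physiology: there is no motor-unit model, no fatigue drift within a
session, and real inter-subject anatomy differences are reduced to the same
distortion family as inter-session shift. Passing tests therefore show that
the pipeline detects and corrects session-level covariate shift of this
kind; they do not certify accuracy levels on recorded human data.

## 6. Benchmark problem sizes

The desk-scale benchmarks (`benchmark_config()`, `reduced_spec()`,
`reduced_schedule()`) fix, once, the following sizes: 8 gestures, 10
subjects × 2 sessions, 4 trials per gesture, 50-frame holds (12-frame
ramps, 25-frame rests); a narrower network with 8 filters per
convolutional/locally connected layer and 32/32/16 fully connected units
(every structural element of the reference architecture is retained);
10-epoch schedules with the learning-rate drops at the proportional
positions (epochs 6 and 9) and at least 50 frames per stream block. The
intra-session arm of the transfer experiment trains to the same number of
gradient updates as the inter-session arm (its split holds about half the
frames), so the comparison reflects the session shift rather than
differential underfitting. The multi-stream comparison uses one subject
with 10 sessions (9 sources), 2 trials × 30 frames, and the *same* total
batch for the classical (M = 1) and multi-stream (M = 9) arms; the two
arms are paired — identical initial weights and batch-composition RNG — so
the comparison isolates the normalization scheme from initialization and
sampling luck (the expected difference between the schemes is small, and
an unpaired design cannot resolve it at this scale).

Five (transfer) or ten (stream comparison) independently seeded replicates
are averaged. `scripts/acceptance.R --seed N --out results/acceptance.json`
recomputes everything from scratch.

## 7. Known limitations

* Pre-training defaults (`pretrained =` argument) are deliberately plain —
  the warm start copies all weights and statistics; nothing is reset.
* The generator's gestures are stationary during the hold; transitional
  motion is explicitly out of scope.
* Adaptation assumes the target session contains a reasonable mix of
  activity; statistics estimated from rest-only frames will match rest, not
  gestures (the calibration-volume experiment shows a 5% random subset
  suffices).
* The implementation is pure R with BLAS matrix products; it is sized for
  the reduced benchmarks, not for training 64-filter networks on millions
  of frames.
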