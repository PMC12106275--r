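---
title: "Methods: wavelet-downsampled subtomogram classification with OOD rejection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet-downsampled subtomogram classification with OOD rejection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryowave)
```

## The problem and the model

Subtomograms cut from cryo-electron tomograms are extremely noisy 3D
density maps, each containing one macromolecule. Two failure modes
dominate conventional CNN classifiers here: aggressive spatial
downsampling (strided convolution, max pooling) aliases high-frequency
noise into the features, and a closed-set softmax classifier forcibly
assigns every unknown particle to some training class. `cryowave`
addresses both with a pipeline of three parts.

### 1. DWT-downsampled residual encoder

One level of the discrete wavelet transform splits a length-`m` signal
into `⌊m/2⌋` low-pass and `⌊m/2⌋` high-pass coefficients. Writing the
analysis filters `l` and `h` into banded matrices `L` and `H` (row `j`
carries the taps at columns `2j + k`), the transform is a matrix
product, and the 3D transform applies it separably along width, height
and depth, producing eight subbands `x_lll … x_hhh`. The encoder keeps
only `x_lll`: a half-resolution, low-pass-filtered volume. Replacing
every spatial halving of a residual network with this operation
downsamples *and* denoises at once; the high-frequency noise that a
strided convolution would alias is simply discarded.

Numerical conventions, fixed once:

* **Boundary handling: periodic.** It keeps `L` and `H` exactly
  `⌊m/2⌋ × m`, and makes the Haar transform orthonormal (energy
  conservation is tested to 1e-9). Symmetric extension is available on
  the convolution path for standalone use.
* **Coefficients.** Canonical published Haar and CDF biorthogonal
  analysis filters (orders 2.2–5.5), low-pass normalised to sum to
  `sqrt(2)`. The retained `x_lll` therefore has a DC gain of
  `2*sqrt(2)` per level, which matters when comparing feature scales
  across configurations.
* **High-pass sign.** `h_k = (−1)^k l_{1−k}` for Haar; the CDF banks
  follow the standard tables. The sign convention is irrelevant
  downstream because only `x_lll` is retained.
* **Odd lengths** are rejected inside the encoder (every preset keeps
  extents even); the standalone `dwt1d()` pads one periodic sample and
  flags the result.
* **Axis order.** Volumes are indexed `(height, width, depth)`; the 3D
  transform runs width first, then height, then depth. For the
  low-pass-only path the three axis transforms commute, and the encoder
  exploits that to reorder them for fewer memory permutations (the
  results agree to machine precision; this is tested).

Each wavelet block runs DWT → 3×3×3 convolution → BatchNorm → ReLU →
(optional second DWT) → convolution → BatchNorm on the main branch, adds
a residual branch (DWT low-pass + 1×1×1 projection + BatchNorm whenever
shape or channels change), and finishes with ReLU. Applying the
two-DWT variant in every block of a four-stage network would shrink a
32³ input by 4⁴ = 256× per axis, which is impossible; the default preset
therefore uses one DWT per stage (32 → 16 → 8 → 4 → 2, widths
64/128/256/512, features pooled to d = 512), and the per-block step
count is configurable (0–2) so the literal two-DWT block remains
available for shallower networks. The stem is a 3×3×3 convolution with
no resolution loss in the default preset. Initialisation is
Kaiming-fan-out for convolutions, unit/zero for BatchNorm, fully
seeded.

A strided-convolution **control mode** (`downsample_op = "conv"`)
replaces every DWT halving with stride on the following convolution and
the residual DWT with strided subsampling, leaving everything else
identical — this is the ablation arm used to test that wavelet
downsampling is what buys noise robustness.

### 2. Adaptive similarity classifier

A single bias-free fully connected layer scores features against one
weight vector per class. On large training sets the logit is the plain
inner product `‖w_c‖‖z‖ cos θ_c`; on small ones the t-vMF similarity

$$\phi(\cos\theta;\tau) = \frac{1+\cos\theta}{1+\tau(1-\cos\theta)} - 1$$

replaces the cosine, mapping `[−1,1]` onto `[−1,1]` monotonically while
compressing everything but well-aligned directions; this shrinks
within-class variance when data are scarce. `select_mode()` switches at
5000 training samples, a boundary chosen so that collections of a few
thousand real particles use t-vMF (τ = 64) while simulation-scale sets
use cosine. The logits retain vector magnitudes, matching the method's
published form; the t-vMF literature more commonly normalises features,
and that variant is available (`normalize_features = TRUE`).

Two practical notes, both discovered during development and handled
explicitly:

* With magnitudes retained and τ large, training *from random
  initialisation* is pathological: at `cos θ ≈ 0` the similarity is
  ≈ −1 for every class, and gradient descent initially reduces the
  target class's weight norm towards collapse. The aggressive-τ
  configuration is intended for long small-data schedules; the
  package's synthetic benchmark (below) uses the cosine mode, which is
  also the mode the method's own simulation-scale experiments use.
* A feature vector can be exactly zero (dead ReLU path). The public
  `classifier_logits()` treats this as an error (cosine is undefined);
  the internal training/inference path clamps the norm at 1e-12 so one
  degenerate sample scores like an unaligned one instead of aborting a
  batch.

Training minimises mean cross-entropy (probabilities floored at 1e-12
under the log) with SGD: 100 epochs, batch 64, learning rate 0.1,
momentum 0.9, weight decay 1e-4 (applied to convolution and classifier
weights, not BatchNorm parameters), constant learning rate. Each
training volume receives one of the 24 proper right-angle cube
rotations per epoch — an exact voxel permutation, no interpolation blur;
continuous rotations with trilinear resampling are available as an
option. Volumes are standardised to zero mean and unit variance before
encoding.

### 3. Mahalanobis out-of-distribution detector

After training, evaluation-mode features of the (augmentation-free)
training set fit one Gaussian per class with a **tied** covariance:
prototypes `μ_c`, pooled within-class covariance normalised by `N`
(exactly as the method defines it, not `N − C`). The confidence score
is `S(z) = max_c −d_M(z, G_c)²` — zero at a prototype, increasingly
negative away from every class. Decisions use `S(z) ≥ λ` (ties accept).

* **Ridge.** With `N ≤ d` the pooled covariance is singular. The
  precision is computed from `Σ + ε·(tr Σ/d)·I` with ε = 1e-3
  (plain `ε I` when `Σ = 0`); this guarantees invertibility and is
  negligible for well-conditioned fits. Distances are affine-invariant
  when ε = 0 (tested to 1e-6).
* **Calibration split.** λ is the empirical `(1 − 0.95)`-quantile
  (lower interpolation) of scores on a held-out stratified 10 %
  validation split, so the achieved acceptance on the calibration set is
  at least the target; training features are the fallback when the
  split is smaller than 20 samples. Calibrating on held-out data avoids
  the optimistic thresholds that training-set calibration produces.
* Scores are on the *squared*-distance scale (score plots and
  thresholds inherit it).

Evaluation reports AUROC (midrank pairwise estimator), FPR95 (threshold
recomputed from the evaluated ID scores, ties count as detections,
independent of the deployed λ) and mixed-set accuracy. The accuracy
accounting on ID+OOD mixtures is: an ID sample is correct iff accepted
*and* correctly labelled; an OOD sample is correct iff discarded. This
is the only reading under which OOD-blind classifiers score near zero
on OOD-heavy test sets, which is the phenomenon the metric exists to
expose. The diagnostic export writes a 2D principal-component embedding
and overlaid score histograms (CSV + PNG); PCA is used for the
embedding because it is deterministic, dependency-free and sufficient
to visualise ID/OOD separation at these feature dimensions.

## The synthetic benchmark

`make_dataset()` renders six structurally distinct density phantoms
(sphere, ellipsoid, cylinder, dumbbell, torus, cross) on a 32³ grid with
a ≥ 2-voxel margin, smooths them with a σ = 1 voxel Gaussian kernel to
emulate band-limited density, applies a random right-angle rotation per
sample and adds zero-mean Gaussian noise with variance
`mean(signal²)/SNR`. Families are split into disjoint ID and OOD sets;
train/validation/ID-test splits contain only ID families.

The package's reference benchmark uses ID = {sphere, dumbbell, torus},
OOD = {ellipsoid, cross} (the OOD set deliberately contains a
near-spherical confounder), 250 samples per family split 0.8/0.1/0.1
(200 training volumes per class), SNR 0.5, and a deliberately small
encoder preset (`"tiny"`: one DWT stem halving, two one-block stages of
16/32 channels, d = 32) trained for 20 epochs — sizes chosen so a full
run takes about a minute on one CPU, which also sets the problem sizes
used by the test suite. Under these conditions the pipeline reaches
ID-test accuracy ≥ 0.90 and OOD AUROC ≥ 0.95 across seeds, and at
SNR 0.3 the DWT encoder's accuracy is at least that of the
strided-convolution control under an identical budget.

What the simulator does **not** emulate: the missing wedge of tomographic
tilt series, contrast transfer function effects, crowding, and realistic
macromolecular shapes. Passing the synthetic benchmark demonstrates that
the pipeline's mechanics (wavelet downsampling, similarity
classification, Mahalanobis rejection, threshold calibration) work as
specified — not that these accuracy levels transfer to real or
SHREC-style data, which require externally downloaded datasets and
longer training.

## Degenerate inputs and tie-breaking

* Argmax ties in prediction resolve to the lowest class index.
* Score ties at λ accept (ID).
* Constant (zero-variance) volumes standardise to all zeros rather than
  dividing by zero.
* Every class must have ≥ 2 training samples; calibration needs ≥ 20
  scores; empty score vectors are errors, not NaNs.

## Known limitations

* Pure-R training is practical at the desk scale this package targets
  (tiny preset, hundreds of volumes); the default depth-18 preset is
  provided for architectural fidelity and inference, but training it on
  real-scale datasets calls for a GPU framework.
* The t-vMF mode with τ = 64 needs long schedules (and benefits from
  `normalize_features = TRUE`) when trained from scratch; see above.
* BatchNorm statistics make training loss depend on batch composition;
  seeded runs are reproducible, but bitwise reproducibility across BLAS
  implementations is not guaranteed (evaluation agrees to ~1e-6).
* MRC I/O supports mode 2 (float32), the mode this pipeline reads and
  writes; integer modes are rejected with a format error.
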