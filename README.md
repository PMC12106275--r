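# cryowave

Noise-robust classification of cryo-electron tomography (cryo-ET)
subtomograms with out-of-distribution (OOD) rejection, in pure R.

## The problem

Cryo-ET tomograms are segmented into small (here 32×32×32 voxel)
subtomograms, each containing one macromolecular particle at a very low
signal-to-noise ratio. A classifier trained on a fixed set of particle
classes will happily mislabel every particle it has never seen — and real
tomograms are full of such unknown species. `cryowave` implements a
classification pipeline that (i) downsamples with the discrete wavelet
transform instead of strided convolution or pooling, so high-frequency
noise is filtered rather than aliased into the features, and (ii) scores
every input against a Gaussian model of the training feature space,
discarding particles that are too unlikely to belong to any known class.

## The method

**Encoder.** A 3D residual network whose blocks replace every spatial
halving with the low-frequency subband of a separable single-level 3D
DWT: `x_lll = L x` applied along width, height and depth, where `L` is
the `⌊m/2⌋ × m` low-pass filter matrix (periodic boundary). Haar and
CDF biorthogonal banks of orders 2–5 (`haar`, `ch2.2` … `ch5.5`) are
provided in both filter-matrix and convolution form.

**Classifier.** A single fully connected layer scored by similarity:
either the plain inner product `‖w_c‖‖z‖ cos θ_c` (large training sets)
or the t-vMF pseudo inner product `‖w_c‖‖z‖ φ(cos θ_c; τ)` with

    φ(c; τ) = (1 + c) / (1 + τ (1 − c)) − 1,

which compresses poorly aligned directions and tightens class clusters
on small training sets (τ = 64 by default). Softmax + cross-entropy,
SGD (lr 0.1, momentum 0.9, weight decay 1e-4, batch 64), random
right-angle rotation augmentation.

**OOD detector.** Class prototypes `μ_c` (per-class feature means) and a
single tied covariance `Σ = (1/N) Σ_c Σ_{i∈c} (z_i−μ_c)(z_i−μ_c)ᵀ` give
the confidence score `S(z) = max_c −d_M(z, G_c)²`, the negated squared
Mahalanobis distance to the nearest class Gaussian. A threshold `λ` is
calibrated on held-out in-distribution data so that 95 % of ID samples
score `S(z) ≥ λ`; anything below is discarded as OOD. Evaluation uses
AUROC, FPR95 (false-positive rate of OOD at 95 % ID acceptance) and
mixed-set accuracy (an OOD sample counts correct iff discarded).

A synthetic phantom simulator (six distinct macromolecule-like density
families, random rotation, additive Gaussian noise at configurable SNR)
makes the whole pipeline trainable and testable without any downloads.

## Worked example

```r
library(cryowave)
ds <- make_dataset(id_families = c("sphere", "dumbbell", "torus"),
                   ood_families = c("ellipsoid", "cross"),
                   n_per_class = 100, snr = 0.5, seed = 1)
m <- ds$manifest
train <- m$split %in% c("train", "val")
fit <- cryowave(ds$volumes[train], m$label[train],
                encoder = encoder_config("tiny", seed = 1),
                config = train_config(epochs = 10, seed = 1),
                mode = "cosine")
print(fit)
#> Subtomogram classification pipeline (cryowave)
#>   classes:            3
#>   classifier mode:    cosine
#>   feature dimension:  32
#>   wavelet bank:       ch3.3
#>   OOD threshold:      -57.9682 (95% TPR, validation set)
#>   final train loss:   0.0003 (10 epochs)

evaluate_pipeline(fit, ds$volumes[m$split == "test_id"],
                  m$label[m$split == "test_id"],
                  ds$volumes[m$split == "test_ood"])
#> Open-set evaluation (30 ID / 200 OOD samples)
#>   AUROC          1.0000
#>   FPR@95%TPR     0.0000
#>   mixed accuracy 0.9783
#>   deployed lambda -57.9682

predict(fit, ds$volumes[m$split == "test_ood"][1:3])[, 1:4]
#>   sample_id      score decision predicted_label
#> 1  sample_1 -1844.5813      OOD              NA
#> 2  sample_2  -640.0683      OOD              NA
#> 3  sample_3  -680.0715      OOD              NA
```

The three unknown-family particles score far below the calibrated
threshold and are discarded instead of being forced into a known class;
the AUROC/FPR95 lines say the ID and OOD score distributions are fully
separated on this benchmark.

A thin command-line interface over the same functions (verbs `simulate`,
`train`, `infer`, `evaluate`, MRC volumes + CSV manifests) is installed
at `inst/cli/cryowave.R`.

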