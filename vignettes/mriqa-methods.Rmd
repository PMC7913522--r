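---
title: "Quality assessment of MR images by network fusion: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality assessment of MR images by network fusion: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Magnetic resonance images degrade in characteristic ways — parallel-imaging
acceleration discards phase-encoding echoes and introduces ghosting and
noise amplification; motion and reconstruction add blur. Radiologists grade
such scans on a 1–5 mean-opinion-score (MOS) scale. A *no-reference* quality
model predicts that grade from the image alone, which is the only setting
available in practice: pristine reference scans of a patient do not exist.

`mriqa` implements a two-stage learned quality model plus the complete
evaluation protocol used to compare such models, and a synthetic benchmark
that makes the whole pipeline testable without clinical data.

## The model

**Stage A — joint transfer learning of a fusion.** Each convolutional
backbone is truncated at its global-average-pooling (GAP) layer: the
classifier stack configured for 1000 classes (fully connected layer,
softmax, classification output) is removed, and what remains maps an image
to a fixed-length pooled feature vector. The backbones share one input
(resized per backbone, bilinear, aspect ratio not preserved — MR slices are
square or nearly so) and are joined by a feature *concatenation* layer,
`x = x_net1 ⊕ … ⊕ x_netM`, followed by one fully connected unit and a
linear regression output. Concatenation, not element-wise addition, is the
only dimensionally consistent fusion here: the pooled widths of the usual
backbones differ (e.g. 2048/1024/512). The whole fusion is trained jointly
under the MSE loss `L = (1/N) Σ (qˢ − qᵒ)²`; a `half` switch provides the
`L/2` convention some frameworks use for regression layers (it only
rescales gradients, so the plain form is the default). Single-channel
16-bit MR images are replicated to three channels and scaled to `[0, 1]`
before entering the network.

Since no deep-learning framework is assumed, the package carries a compact
CNN engine: 3×3 same-padding convolutions via precomputed gather indices
(im2col) and BLAS products, ReLU, 2×2 average pooling, GAP, and SGDM with
per-epoch reshuffling. The seven canonical recognition backbones are
registered with their true pooled widths and input sides (so width
arithmetic and presets like `R50GR18` = 2048+1024+512 = 3584 are exact);
materializing one with `weights = "random"` builds a schematic,
depth-reduced stack with the same interface, and `weights = "pretrained"`
expects externally supplied ImageNet weights, which are optional inputs
never required by the tests. `tiny_backbone()` registers small 64-pixel
stacks that make desk-scale experiments cheap.

**Stage B — ε-SVR quality model.** The concatenated GAP features of the
trained fusion, min–max scaled per dimension with a scaler fitted on the
training fold only (RBF kernels need comparable scales; freezing the scaler
avoids test-set leakage), feed an ε-support-vector regression with RBF
kernel `c(xₙ, x) = exp(−γ‖xₙ − x‖²)` (Euclidean norm — the standard RBF
definition). Predictions evaluate `f(x) = Σ tₙ c(xₙ, x) + b` directly from
the stored dual coefficients. The dual problem is solved by libsvm (e1071)
behind this interface with a tight KKT tolerance; the test suite checks the
solution against an independent interior-point quadratic-programming
oracle. Hyperparameters are selected by grid search maximizing 5-fold
cross-validated Spearman correlation on the training fold, ties broken
towards smaller `C`, then smaller `γ` (preferring the smoother model). The
full grid is `C ∈ 2^{−3..9}`, `γ ∈ 2^{−15..3}`, `ε ∈ {0.01, 0.1, 0.5}`;
the protocol default is a compact sub-grid (`C ∈ 2^{−1,1,3,5}`,
`γ ∈ 2^{−9..−1}`, `ε ∈ {0.01, 0.1}`) spanning the same orders of magnitude
at a fraction of the cost. Features come from the last training epoch.

## Evaluation protocol

SRCC and KRCC are computed on raw predictions; PLCC and RMSE after the
five-parameter logistic mapping
`Qᵒ′ = β₁(½ − 1/(1+exp(β₂(Qᵒ−β₃)))) + β₄Qᵒ + β₅`, fitted per evaluation on
the test-fold pairs by Levenberg–Marquardt least squares from the
initialization `β = (range(Qˢ), 1/sd(Qᵒ), mean(Qᵒ), 1, 0)`. The family
contains the identity (`β₁ = 0, β₄ = 1, β₅ = 0`); whenever the optimizer
fails or ends above the identity's residual, the identity parameters are
returned, so the mapping can never degrade the raw scores. SRCC uses the
classical rank-difference formula on tie-free data and Pearson correlation
of average ranks under ties; KRCC counts concordant/discordant pairs
exhaustively with tied pairs counting as neither while the denominator
keeps all pairs (tau-a — users comparing against tau-b implementations
should expect differences on tied data).

Train/test splits are drawn at *group* granularity: the acquisition
experiment (patient × body part; `group_id`) is the unit of disjointness,
`round(0.8·G)` groups (round-half-up) train and the rest test, and medians
over 10 iterations are reported. Rotation augmentation (bilinear, zero
fill, angles `k·step` up to 360° so the full-turn member doubles as the
retained unrotated copy) is applied to training folds only, and by default
only when the training set is small (< 100 images) — augmenting a
sufficiently large set mainly costs time. Method comparison uses one-sided
Wilcoxon rank-sum tests in both directions at `α = 0.05` on the
per-iteration SRCC samples, scoring +1/0/−1 into an antisymmetric matrix
whose row sums rank methods globally.

## The synthetic benchmark

Phantoms are 5–12 smoothly shaded random ellipses normalized to the full
16-bit range. Three schematic degradations emulate how accelerated MR
acquisition damages images: `undersample_ghost` zeroes
`floor(severity·h)` randomly chosen non-DC k-space lines and reconstructs
the magnitude image (ghosting/ringing); `rician_noise` takes the magnitude
of the complex signal plus Gaussian noise of SD `severity·0.12·65535` in
both quadratures (the MR magnitude-noise model); `gaussian_blur` smooths
with SD `severity·4` pixels. The default benchmark mirrors a 240-image
clinical collection: 30 groups × 2 phantoms × 4 severities, with the
severity ladder `c(0, 0.2, 0.6, 1)` mapping a four-step acceleration
series that loses 30/40/60/80 % of the echo signal onto `[0, 1]` relative
to its best acquisition (`(loss − 30)/50`). The composite default
distortion applies ghosting at full severity plus Rician noise at `0.5·s`
and blur at `0.3·s`, the co-occurring artifacts of acceleration.
Pseudo-MOS is linear, `5 − 4·severity`, with ±0.2 seeded uniform jitter
standing in for radiologist averaging noise; adjacent severity levels stay
separable, so per-level mean MOS is strictly monotone. All randomness
derives from one master seed through per-image child seeds, making
regeneration bit-exact.

What the benchmark does *not* emulate: anatomy, coil sensitivity profiles,
non-Cartesian trajectories, scanner-specific reconstruction, or the
perceptual weighting radiologists apply. Passing the synthetic recovery
study therefore shows that the pipeline's machinery — feature learning,
SVR, protocol — recovers a known monotone quality signal under MR-like
distortions; it does not certify clinical performance, which requires real
scored data.

## Numerical choices and degenerate inputs

* Training defaults follow the standard fine-tuning recipe (SGDM, learning
  rate 1e-4, batch 32, 5 epochs, momentum 0.9; no schedule, decay, or
  early stopping). The desk-scale protocol uses learning rate 0.02 for the
  randomly initialized tiny fusions — calibrated on training-loss descent
  only — because the small transfer-learning rate exists to preserve
  pretrained weights, of which a random init has none. Head weights start
  from a small-variance seeded normal with bias 3.0 (mid MOS scale), which
  centers initial predictions.
* The reproduction study (`scripts/acceptance.R`) uses 40 groups × 5
  severity levels of 64-pixel phantoms and 10 protocol iterations — sizes
  at which the full pipeline
  (10 fresh fine-tunings plus SVR searches) completes in a few minutes on
  one CPU while leaving ~40 test images per fold for stable rank
  statistics.
* Constant predictions make rank correlations undefined; the protocol
  surfaces this as a "degenerate prediction" error rather than emitting
  NaN. Constant SVR targets yield the closed-form solution (all `tₙ = 0`,
  `b` = target). Min–max scaling maps constant feature columns to zero.
* DICOM reading applies rescale slope/intercept when present and clips to
  `[0, 65535]`, canonicalizing vendor dialects; 16-bit PNG encoding is
  implemented in-package (zlib via `memCompress`, table-driven CRC-32)
  because no installed encoder writes 16-bit grayscale PNG.
* Image read/write round trips are bit-exact for 16-bit PNG, TIFF, and
  DICOM, and the group label defaults to the filename stem before the
  first underscore when no metadata provides one.

## Known limitations

* The schematic stand-ins for named ImageNet backbones reproduce interface
  (input side, pooled width) but not depth or pretrained representations;
  conclusions about *which* backbone fuses best require the real weights.
* Reproducibility is bitwise only per platform/BLAS; tests therefore
  assert statistical properties of training, not bitwise weight equality
  across platforms.
* KRCC is tau-a by construction (see above); SRCC falls back to Pearson-
  of-ranks under ties.
* Whether an epoch should count the augmented or the source images is a
  convention; here one epoch is one pass over the (possibly augmented)
  training set as given to `fine_tune()`.
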