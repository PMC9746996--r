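---
title: "Methods: gradient-direction co-occurrence classification of cell images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gradient-direction co-occurrence classification of cell images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdglcm)
```

## The model

The package classifies segmented cell crops (healthy versus dying neurons)
from second-order texture statistics of their *gradient* maps rather than
their raw intensities. The chain is:

1. **Gradient maps.** For grey map `f`, central differences give
   `g_x = ∂f/∂x` (columns) and `g_y = ∂f/∂y` (rows, increasing downward),
   with one-sided differences at the borders; magnitude
   `|g| = sqrt(g_x² + g_y²)`; direction `α = atan2(g_y, g_x)` in `(-π, π]`.
   Pixels with `g_x = g_y = 0` get direction 0 so no NaN enters the
   pipeline. A Sobel scheme is available behind `scheme = "sobel"`, and a
   second direction convention `atan(g_x / g_y)` in `(-π/2, π/2]` behind
   `direction_convention = "transposed"` — the transposed arctangent ratio that
   appears in parts of the texture literature. We default to `atan2`, the
   standard image-gradient direction; neither reading is asserted as the
   "true" one, both are reproducible.

2. **Quantization.** The chosen map (direction, magnitude, or raw
   intensity) is linearly binned to `N ∈ {8, 16, 32, 64}` integer levels.
   Default policy is per-image min–max: the in-mask minimum and maximum span
   the bins, making the representation invariant to any affine rescaling of
   the map — the property that underwrites robustness to global
   staining-intensity changes. A constant map maps to level 1. Masked-out
   pixels carry `NA` and never enter co-occurrence counts.

3. **Co-occurrence.** For displacement `(d, θ)` with `d = 1…15` and
   `θ ∈ {0°, 45°, 90°, 135°}`, `p(i, j)` counts in-mask pixel pairs with
   levels `(i, j)` at that displacement, in both the forward and reverse
   direction (so `p` is symmetric). Offset groups 1/2/3 use the nested
   distance sets `{1..4}`, `{1..8}`, `{1..15}` — 16, 32, 60 GLCMs per cell.
   The distance subsets for groups 1 and 2 are a design choice (only the
   cardinalities are fixed by the problem statement); nested smallest
   distances are the natural reading. The matrices are normalized to
   relative frequencies by default, which removes the dependence of count
   magnitudes on cell area. An `N × N` GLCM is the same size for a 20 px
   and a 100 px cell: this is the device that turns variable-size crops
   into fixed-length classifier inputs.

4. **Classifiers.** Each flattened GLCM (row-major, length `N²`) is one
   training sample carrying its cell id — the hidden-layer sizing rule
   (below) only makes sense if the input layer is a single GLCM, so the
   `k` GLCMs of a cell act as data augmentation. Three families:
   - **SLP**: linear predictor trained by the LMS rule
     `W(n+1) = W(n) + μ e(n) X(n)`, `e = d − y`, `y = WᵀX`, `μ = 0.1`,
     no hard threshold. A linearity probe.
   - **MLP** with 1 or 2 hidden layers, sigmoid on hidden and output
     units, two output neurons (healthy, dying) as a multi-label head.
     Hidden widths follow the halving rule `input/2` (and `input/4`):
     64→32(→16), …, 4096→2048(→1024). The width-10 Haralick input rounds
     the halves up (5, 3) under `allow_odd = TRUE`.
   - Training: scaled conjugate gradient (batch) by default, or the
     textbook per-sample steepest-descent backprop updates
     (`optimizer = "backprop"`). Early stopping splits 20% of the training
     data off (the 80:20 split), checks validation loss every iteration,
     and stops after 5 consecutive checks without improvement, returning
     the best-validation weights.

5. **Baseline ("standard method").** GLCMs from the intensity-quantized
   map, each reduced to the ten Haralick statistics (contrast, energy,
   entropy, homogeneity, variance, sum average, sum variance, sum entropy,
   difference variance, difference entropy), z-scored with training-fold
   statistics only, into a 2-hidden-layer MLP.

6. **Evaluation.** Seeded 5-fold cross-validation (optionally grouping all
   GLCMs of a cell into one fold to prevent within-cell leakage);
   sensitivity `TP/(TP+FN)`, selectivity `TP/(TP+FP)` and accuracy in
   percent, with "dying" the positive class; one ROC and trapezoidal AUC
   per class. An undefined metric (zero denominator) is reported as `NA`
   — classification failure is a recordable outcome, not an error.

## Numerical and definitional choices

- **Haralick definitions** are pinned as follows, because the literature is
  ambiguous on exactly these points: all entropies use the natural log with
  `0·log 0 := 0`; *variance* is the sum-of-squares about the GLCM mean
  `μ = Σ i p(i,j)`; *sum variance* is the variance of the diagonal-sum
  marginal `p_{x+y}` about the sum average (not about the sum entropy,
  widely considered a typographical slip in the original formula table);
  *difference variance* is the variance of `p_{x−y}` about its own mean.
- **Loss**: cross-entropy with sigmoid outputs by default (output delta
  `y − t`); `loss = "mse"` reproduces the textbook `y(1−y)e` delta exactly.
  Both pass a central-difference gradient check at 1e-6 relative error.
- **Weight initialisation**: symmetric uniform scaled by `1/sqrt(fan-in)`,
  seeded; identical seeds give bit-identical models.
- **SCG hyperparameters** follow the published defaults
  (`σ₀ = 1e-4`, `λ₀ = 1e-6`).
- **Degenerate inputs**: an offset that does not fit a cell yields an
  all-zero GLCM with a warning (never a crash), keeping per-cell sample
  counts constant; an all-zero GLCM contributes a zero Haralick row;
  constant maps quantize to level 1; empty masks and single-class label
  vectors raise errors naming the problem.
- **No smoothing filter** is applied before gradient computation: smoothing
  blurs exactly the fine direction structure the method feeds on.

## The synthetic world

The motivating image collections (stained brain sections from large-animal
hypoxia models) are not publicly distributable, so the package's test
surface is a generator whose *stated world* is fixed here once:

- 500 cells per class by default (the scale of the motivating data),
  sides uniform on 20–100 px, elliptical masks (minor axis kept ≥ 16 px so
  every cell admits `d = 15` along some axis).
- **Healthy recipe**: a radial intensity ramp with a darker off-centre
  nucleus over a smoothed random staining field (σ = 3 px, a fixed granule
  scale in pixel units). Neighbouring gradient directions agree: mean local
  circular dispersion ≈ 0.29.
- **Dying recipe**: the same background plus dense granular impulses
  (density U(0.5, 0.8), contrast U(0.1, 0.2)) — fragmented, condensed
  chromatin. Isolated intensity flips leave co-occurrence of the intensity
  map relatively close to healthy, but scramble the derivative field around
  every hit: dispersion ≈ 0.64. The designed class margin in dispersion is
  at least 0.15.
- **Staining nuisance**: every cell is passed through a random monotone
  tone curve (gamma `e^U(−1.1, 1.1)`) and contrast depth U(0.35, 0.9).
  Gradient *direction* is exactly invariant to monotone intensity
  transforms; intensity and magnitude statistics are not. This is the
  mechanism by which the raw-intensity baseline is honestly degraded, and
  it mirrors the real nuisance (stain-procedure-dependent intensity) that
  motivates gradient representations in the first place.
- **Intensity overlap**: per-cell mean intensity is drawn from class
  distributions with means `0.5 ± 0.05(1 − overlap)`, default overlap 0.8;
  at overlap 1 the distributions coincide and a mean-intensity threshold
  classifies at chance (asserted ≤ 60% on 200 cells).
- Additive sensor noise, sd 0.02 on the 0–1 scale — a moderate level for
  high-SNR brightfield imaging.

**What a green test establishes — and does not.** The generator reproduces
the *qualitative contrast* the method exploits (direction-coherent vs
direction-disordered interiors under an intensity confound), with
difficulty parameters chosen once, not calibrated against any real tissue.
End-to-end results on it demonstrate that the pipeline extracts the
direction signal and that the orderings hold in this world (gradient-
direction method ≈ 96–97% cell-level accuracy, above the ten-feature
Haralick baseline's 92–94%); they do not certify performance on real
histology. Two real-data features are deliberately absent: cross-animal
dependence (there are no "animals" to hold out) and touching/overlapping
cells (segmentation is assumed done).

## Open-design decisions

- **Metric granularity.** Metrics are computed at two granularities in
  every report: per GLCM sample (the training unit) and per cell (mean
  score over a cell's GLCMs). The per-cell numbers are the headline: the
  biological unit of classification is the cell, and individual offsets —
  a single `d = 1` GLCM of a small cell — are genuinely ambiguous, which
  caps per-sample accuracy around 91% in the synthetic world while cell
  pooling reaches ≈ 97%.
- **Fold granularity.** Default folding randomises samples, matching a
  protocol that randomises all cells into one dataset; `group_by_cell =
  TRUE` keeps each cell's GLCMs in one fold and is the stricter option
  (the within-cell dependence is a known leakage channel; per-animal
  splitting has no synthetic analogue).
- **ROC averaging**: per-fold AUCs are averaged arithmetically; fold ROC
  point lists are returned per fold rather than vertically averaged.

## Known limitations

- In the synthetic world the gradient-direction GLCM classes are close to
  linearly separable: the SLP (with normalized relative-frequency inputs)
  ranks essentially as well as the shallow MLPs (cell-level AUC ≈ 0.986
  for both). The catastrophic linear-probe failure seen on real tissue
  does not reproduce here; a plausible mechanism for the real failure —
  LMS at `μ = 0.1` on unnormalized, high-dimensional co-occurrence counts
  — disappears under the package's default GLCM normalization. The
  corresponding acceptance assertion is left failing rather than
  engineered to pass.
- The two-hidden-layer MLP offers no measurable gain over one hidden layer
  here, consistent with the shallow-suffices finding it probes.
- Haralick feature values depend on the pinned definitional choices above;
  other software pinning different variants (log base 2, the literal
  sum-variance formula) will differ numerically.
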