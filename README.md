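# gdglcm — gradient-direction co-occurrence texture classification of cell images

`gdglcm` classifies segmented histology cell crops — healthy versus dying
neurons in stained brain-tissue sections — without hand-engineered texture
features. The problem it addresses: cell crops vary in size (roughly 20–100
pixels a side) while neural-network classifiers need a fixed-length input,
and raw staining intensity varies with the staining procedure rather than
with cell state, so brightness is an unreliable feature.

The method: compute the image gradient of each cell's grey map,

- gradient vector `(g_x, g_y) = (∂f/∂x, ∂f/∂y)`,
- magnitude `|g| = (g_x² + g_y²)^½`,
- direction `α(x, y) = atan2(g_y, g_x)`,

quantize the direction (or magnitude) map to `N ∈ {8, 16, 32, 64}` grey
levels, and count grey-level co-occurrence matrices (GLCMs) `p(i, j)` over a
grid of displacements — distances `d = 1…15`, angles `θ ∈ {0°, 45°, 90°,
135°}`, counted in both directions so the matrices are symmetric. A GLCM is
`N × N` regardless of cell size, so each vectorised GLCM is a fixed-length
classifier input; the 16/32/60 GLCMs of one cell (offset groups 1/2/3) act
as data augmentation. Gradient *direction* is exactly invariant to monotone
staining-intensity transforms, which is why its co-occurrence statistics
travel better than raw intensity.

Classifiers: a single-layer perceptron (LMS rule `W ← W + μeX`, linear
activation, a linearity probe), and 1- and 2-hidden-layer sigmoid MLPs sized
by the halving rule (hidden widths `input/2`, `input/4`; e.g. 64×64 GLCM →
4096 → 2048 → 1024 → 2), trained by scaled conjugate gradient with early
stopping after 5 failed validation checks (80:20 internal split). The
conventional baseline ("standard method") reduces each intensity GLCM to
ten Haralick statistics (contrast, energy, entropy, homogeneity, variance,
sum average, sum variance, sum entropy, difference variance, difference
entropy) fed to a 2-hidden-layer MLP. Evaluation is 5-fold cross-validation
reporting sensitivity, selectivity and accuracy (percent) plus one ROC/AUC
per class, at both per-GLCM-sample and per-cell granularity.

Because the motivating animal dataset is not public, the package ships a
synthetic generator: two classes of variably sized elliptical cells over a
common smooth staining background, where dying cells carry dense granular
fragmentation impulses (disordering gradient directions) and every cell
passes through a random monotone staining tone curve (confounding raw
intensity statistics). See the vignette for what this emulates and what it
does not.

## Worked example

```r
library(gdglcm)

cells  <- generate_dataset(synth_config(n_per_class = 50, seed = 42))
report <- evaluate_config(cells, method = "gd", N = 8, group = 1,
                          arch = "mlp1", seed = 42,
                          train_cfg = train_config(max_epochs = 200, seed = 42))
print(report)
#> <eval_report gd N=8 group=1 mlp1, 5-fold seed=42>
#>   accuracy    91.00% +/- 1.99
#>   sensitivity 96.02%  selectivity 87.45%
#>   AUC healthy 0.9372  dying 0.9372
#>   per-cell: accuracy 96.93%  AUC healthy 0.9847  dying 0.9847
```

The first block is per-GLCM-sample: every one of the 1600 vectorised GLCMs
(100 cells × 16 offsets) is scored on its own, and individual offsets can be
genuinely ambiguous. The per-cell line pools the 16 scores of each cell by
their mean before deciding — the unit that matters biologically — and is the
headline number. The same call with `method = "standard", arch = "mlp2"`
runs the ten-feature Haralick baseline, which lands below the
gradient-direction method here (92.63% per-cell accuracy versus 96.93%).

A full comparison sweep:

```r
res <- run_experiment(cells, methods = c("gd", "gm", "standard"),
                      levels = c(8, 16), groups = 1, archs = c("slp", "mlp1"),
                      seed = 1)
res$summary   # tidy data.frame: one row per configuration
```

Command line (after install; `exec/gdglcm` in the installed package):

```sh
gdglcm simulate --n-per-class 100 --seed 1 --out cells/
gdglcm evaluate --in cells/manifest.csv --methods gd,standard \
                --levels 8 --groups 1 --arch mlp1 --seed 1 --out results/
```

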