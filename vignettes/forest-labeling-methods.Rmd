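---
title: "Unsupervised forest labeling and downscaled U-Nets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised forest labeling and downscaled U-Nets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models implemented in `forestseg`, their
assumptions, the tunable parameters, the design choices that were
genuinely open, and what the synthetic-scene experiments do and do not
demonstrate.

## 1. The labeling model

### Pixel mixture

Each pixel of a 4-band raster (red, green, blue, near-infrared, 8-bit
levels) is treated as an i.i.d. draw from a K-component multivariate
Gaussian mixture. Spatial context enters only later, through the merge
rule and the mask filters. This is a deliberate simplification: land
covers are spectrally clustered, and the near-infrared band separates
dense healthy vegetation strongly, so a purely spectral mixture already
produces usable clusters at survey scale.

`fit_gmm()` runs expectation–maximization with:

* **kmeans++-style seeding** of the component means from the given seed,
  so fits are exactly reproducible;
* **multi-start** (`n_init = 3` by default): EM is prone to local optima
  as K grows; the run with the best final log-likelihood is kept;
* **ridge regularization** `1e-6` on every covariance diagonal, raised
  temporarily if a component degenerates (recorded on the model);
* **full covariances** by default (`covariance_type = "diagonal"`
  available); the free-parameter count `k` used by the information
  criteria documents both conventions:
  `(K−1) + Kd + Kd(d+1)/2` (full) and `(K−1) + 2Kd` (diagonal);
* convergence when the relative log-likelihood change drops below
  `tol = 1e-6` (at most `max_iter = 200` iterations). The per-iteration
  log-likelihood trace is stored and is non-decreasing up to the ridge's
  numerical effect.

Fitting may subsample pixels (seeded, `sample_size` in `scan_k()`),
because the criterion curve is about relative fit; prediction always
covers every pixel.

### Choosing K

`scan_k()` fits K = 2…10 and tabulates `AIC = 2k − 2 ln L` and
`BIC = k ln N − 2 ln L` on the fitting sample. The likelihood entering
both is the standard mixture log-likelihood (sum over pixels of the log
of the weighted component densities). A regression-style Gaussian
log-likelihood with explicit targets, predictions, and known variance is
provided separately as `gaussian_regression_loglik()` for completeness;
it is not used in model selection because unsupervised clustering
supplies neither targets nor a known noise variance.

`select_k_elbow()` implements the elbow rule: the criterion keeps
decreasing with K, so the selected K is where the decrease slows the most
— the interior point maximizing the second difference
`C(K−1) − 2C(K) + C(K+1)`, ties broken toward smaller K, with a manual
override. The rule is honest about its limits: when the criterion curve
is smoothly convex (cluster structure is hierarchical rather than flat),
the maximal-curvature point sits early and the "true" K is genuinely
ambiguous.

### Merging clusters into forest / no-forest

Forest canopies are not spectrally uniform: tree-height variation casts
shadows, so forest pixels split into a bright-NIR lit cluster and a dark
shadow cluster. Merging those two clusters is traditionally done by
visual inspection; `auto_merge_rule()` formalizes the judgment (and
flags itself as an automatic formalization in the rule's metadata):

* the **seed** is the component with the highest NIR mean;
* any other component joins the forest when (a) its 4-neighborhood
  adjacency score `A(i)` — boundary pixel pairs shared with the seed,
  divided by the component's pixel count — reaches
  `adjacency_threshold = 0.10`, and (b) its visible luminance (mean of
  the R, G, B means) is below the seed's (the shadow criterion).

The adjacency requirement captures "interleaved with the canopy"; the
darkness veto stops bright covers (crops, bare soil) that merely abut
forest from being absorbed. A `manual_merge_rule()` bypasses the
automation.

### Mask filtering

`postprocess_mask()` applies a median filter, then a morphological
closing (dilation followed by erosion, forest as foreground). Both use
square kernels with edge-replication padding, implemented exactly via
integral images. The "9-pixel kernel" convention is read as a 9 × 9
window — the default — but a 3 × 3 (= 9 pixels) reading is one
configuration flag away (`median_size = 3`, `closing_size = 3`). Closing
with a 9 × 9 element fills voids up to ~8 pixels across, matching the
withered-tree holes the filters exist to remove; it also erases true
non-forest gaps of that size, which is the accepted cost.

### Ranking labeled images

`davies_bouldin()` scores each labeled image:
`DB = mean_i max_{j≠i} (sigma_i + sigma_j) / d(c_i, c_j)` with class
centers `c_i` and mean-distance dispersions `sigma_i`; for two classes
this is `(sigma_0 + sigma_1) / d(c_0, c_1)`. Lower is better. The index
is used in its standard positive form (the sign convention follows
"lower is better"; a negated form would invert the ranking). Images where
a class is empty are excluded with a logged reason rather than scored.

## 2. The downscaled U-Net family

`unet_spec()` describes the architecture by one base width `b`: four
encoder blocks `(b, 2b, 4b, 8b)` of two 3 × 3 same-padded convolutions
each (ReLU), 2 × 2 max-pooling between blocks, a `16b` bridge, and four
decoder blocks `(8b, 4b, 2b, b)` fed by 2 × 2 upsampling plus
concatenation with the matching encoder output, ending in a 1 × 1
sigmoid output. Dropout (default rate 0.5, configurable) follows the
encoding path. The six scenarios use `b = 64, 32, 16, 8, 4, 2`.

**Upsampling semantics.** The architecture text reads as a parameter-free
2 × 2 upsampling, but the family's reference parameter totals are
reproduced exactly only by a learnable 2 × 2 transposed convolution that halves the
channel count before concatenation. The ledger was used as the oracle to
reconcile the two readings before the model was built:
`transposed_halving` (default) gives `7574 b² + 144 b + 1` parameters at
4 input channels, which matches every reference scenario total;
`plain_upsample` is kept as an option with its own honest ledger:
its upsampling rows carry zero parameters, but the first decoder
convolution then sees the full incoming channels plus the skip, so the
mode's total differs from (and slightly exceeds) the transposed one.

`count_parameters()` walks the layers symbolically (`k² c_in c_out +
c_out` per convolution) and `build_model()` asserts that the tensors it
actually allocates sum to the ledger total — a hard internal-consistency
error otherwise, so the analytic table can never drift from the runtime
model.

**Training.** The package implements the forward and backward passes on
BLAS matrix products (im2col convolutions) and optimizes binary
cross-entropy (probability clamp `1e-7`) with Adam
(`beta1 = 0.9`, `beta2 = 0.999`), exactly the recurrence exposed as
`adam_reference_step()`, which doubles as the oracle verifying the
training loop. Weight initialization is He-normal; everything stochastic
(initialization, shuffling, dropout) derives from one seed.

**Learning rate.** The default `alpha = 1e-4` is a conventional choice
for long training schedules (thousands of optimizer steps, where larger
rates overfit or oscillate). Desk-scale runs in this package are far
shorter — 200 tiles for 5 epochs is ~65 steps — and Adam's per-parameter
step magnitude is bounded by `alpha`, so moving a logit by O(1) in 65
steps needs `alpha ≈ 1/65`. The desk-scale experiments therefore use
`1e-2`, chosen by that argument, not by sweep. At such short horizons the
long-schedule ordering of rates (where `1e-2` underperforms) need not
reproduce, and the package does not assert it; `lr_sweep()` exists to
measure the ordering for any given budget.

**Batch size** defaults to 16 — a configuration value, not a measured
claim. **Threshold** 0.5 converts the sigmoid probability map to a mask.

## 3. The synthetic scene generator

`generate_scene()` emulates what the labeling pipeline assumes about
survey imagery:

* **contiguous land-cover patches** — a seeded Gaussian random field,
  smoothed (sigma = size/12) and rank-thresholded so class proportions
  are exact; a Voronoi layout is the alternative;
* **five covers** (forest 40%, crops 20%, bare land 16%, orchard 12%,
  settlement 12%) with documented package-defined spectra. The defaults
  deliberately reproduce the cluster structure observed in real imagery:
  lit forest carries the highest NIR mean of all classes; orchard and
  crops form one loose vegetation group and bare land and settlement one
  bright group, so a scene has about four natural spectral clusters, two
  of which are forest;
* **forest as two subpopulations** — lit canopy `(45, 90, 50, 200)` and
  shadow `(18, 32, 20, 90)` (elementwise darker), with spatially
  contiguous shadow patches covering `forest_shadow_fraction = 0.35` of
  the forest;
* **withered-tree holes** — disks of radius 1–3 pixels reassigned to
  bare land inside forest, at `hole_rate = 0.3` expected holes per 1,000
  forest pixels;
* **sensor noise** — additive i.i.d. Gaussian (`noise_sd = 5` levels),
  then clipping to [0, 255] (8-bit radiometric resolution; no
  wrap-around) and rounding.

`separable_scene_spec()` is a deliberately cleaner variant for
model-selection studies: k well-separated classes, no shadows or holes.
Its class means were chosen (within realistic spectral ranges) to make
the pairwise separations as even as possible, because an elbow criterion
is only well-posed when the true structure is flat rather than
hierarchical; forest's extreme NIR keeps perfect equality out of reach.

**What the synthetic experiments show — and don't.** Scenes are
Gaussian by construction, so the mixture model is correctly specified;
real canopies have texture, mixed pixels, anisotropic illumination, and
non-Gaussian tails. Passing the synthetic studies therefore demonstrates
that the machinery (EM, criteria, merging, filtering, ranking, training)
is correct and internally consistent, not that the pipeline reaches any
particular accuracy on real imagery.

## 4. Numerical choices and degenerate inputs

* Cluster-assignment ties go to the lowest component index; maxpool ties
  route gradients to the first window position; elbow ties to smaller K;
  ranking ties to the lexicographically smaller image id.
* Covariance degeneracy is handled by ridge escalation, never by
  dropping components.
* Binary masks through the filters use exact integer integral-image
  sums; no floating-point thresholds.
* A merge rule covering every component yields an all-forest mask with a
  warning (degenerate but representable).
* Non-divisible extents are cropped, never padded. Region cutting
  discards the trailing remainder (`floor(H/s)` regions per axis). Tile
  extraction is stricter: when the extent is not an exact multiple of
  the tile, the partial remainder *and* the adjacent full tile are both
  discarded, so only tiles clear of the cut edge survive — a 4,000-pixel
  extent at tile 128 keeps pixels 1–3,840 and yields 900 tiles per
  image, 14,400 over a 16-image corpus.
* Rasters are held as raw bytes (one per sample), so a 20,000 × 20,000
  4-band extent costs 1.6 GB and the survey-scale tiling arithmetic runs
  in ordinary memory.

## 5. Problem sizes used in the checks

The test suite exercises the survey-scale behaviors at desk scale: ten
128-pixel default scenes for labeling agreement (mean ≥ 0.95 against
ground truth), twenty 128-pixel four-class scenes for elbow recovery
(≥ 90% select K = 4), two hundred 64-pixel tiles / five epochs for
training convergence (> 0.9 training accuracy), and a ten-scene noise
sweep for the Davies–Bouldin ranking (strictly increasing in noise).
Criterion scans subsample 3,000 pixels per image. The exact
architecture arithmetic (kernels, parameters, tiling counts) is tested
at full survey scale, since it is memory-light.

## 6. Known limitations

* The per-pixel mixture ignores texture; covers distinguished only by
  texture will not separate.
* The automatic merge rule assumes shadow clusters are darker *and*
  interleaved with the canopy; sunlit terrain bordering forest on one
  side is handled by the luminance veto, but dark non-forest covers
  threaded through forest (rivers in shadow) would merge incorrectly.
* The elbow rule inherits the ambiguity of hierarchical cluster
  structures; the manual override exists for exactly that case.
* `plain_upsample` changes the parameter ledger; the reference totals are
  only reproduced under `transposed_halving`.
* Training is CPU-bound R; it is sized for method verification, not for
  production-scale fitting.
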