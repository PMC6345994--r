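---
title: "Methods: label-free hyperspectral cell classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free hyperspectral cell classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `hyperclass`, the
assumptions behind them, the tunable parameters and their defaults, what the
synthetic data generator does and does not emulate, and the numerical
choices made where the procedure left freedom.

## The problem

Differentiated neural stem cell (NSC) cultures contain neurons and glia.
Transmission hyperspectral microscopy records, for every pixel, a spectrum
across narrow wavelength bands; the per-pixel spectrum plus local morphology
carries enough signal to assign each pixel to one of four classes — neuronal
cell body (code 1), glial cell body (2), process of either cell type (3), or
the external region (0) — without any label. Code 255 marks pixels excluded
from training and evaluation (in real data: ambiguous cells such as
double-positive or double-negative ones; in this package also pixels whose
flat-field denominator is invalid).

## Flat-field correction and band selection

The corrected stack is `FFC = (O - D) / (F - D)` per pixel and band, where
`O` is the raw object stack, `D` a dark frame (light path shuttered) and `F`
a flat-field reference (illumination without specimen). Because the
illumination field multiplies both `O - D` and `F - D`, it cancels exactly;
the dark offset is removed additively. Pixels where `F - D <= 0` (possible
for isolated pixels under sensor noise) cannot be corrected; they are set to
0 and recorded in an `invalid` mask that downstream training and metrics
treat like the ignore label. We deliberately do not raise an error for them:
a single hot pixel should not abort a batch run. Saturated pixels receive no
special handling beyond this mask.

Band selection is by exact integer-nm match with no interpolation — the
instrument acquires on a fixed grid (63 bands, 420–730 nm at 5 nm), and the
analysis uses the 25 bands from 450 to 690 nm at 10 nm.

## Spectral k-means and the cluster image

All corrected spectra (pooled over the training images of a fold) are
clustered with k-means: k-means++ seeding, then a fixed 30 Lloyd updates
with Euclidean distance over the 25 band values. Design choices:

- **Fixed iteration count, no early exit.** Once converged, extra updates
  are idempotent, so a fixed count is harmless and keeps runs reproducible.
- **Empty clusters** are re-seeded with the point farthest from its current
  centroid, keeping the cluster count exactly `k`.
- **`k = 32`** is the evaluation default; 16–64 is the useful range on these
  images. Larger `k` resolves more subcellular spectra at the cost of noise
  chasing.
- **Assignment ties** go to the lowest cluster index.
- `fit_kmeans` accepts a uniform seeded subsample cap (`run_loo` exposes
  `kmeans_sample_cap`, default 10^6 spectra) because full-resolution image
  sets can exceed memory; at the problem sizes used here the cap is
  inactive.

The *cluster image* maps each pixel to its cluster's **intensity rank**:
clusters are ranked by centroid mean over the 25 bands (rank 0 = darkest)
and the rank is scaled linearly to 8 bits. The mapping from "cluster average
intensity" to pixel value is not uniquely determined by the procedure we
follow; rank-then-scale was chosen because it is monotone in cluster
brightness, spreads values uniformly regardless of `k`, and is invariant to
permutations of cluster indices. Feature extraction operates on this display
channel, not on the nominal cluster ids.

## Multi-scale morphological features

Eight planes per scale — raw intensity, the Hessian components
H~xx~, H~yy~, H~xy~, its eigenvalues λ₁ ≥ λ₂, the Laplacian being H~xx~+H~yy~
(stored implicitly through those two), local standard deviation, and the
circular standard deviation of gradient orientations — at scales 1, 1/2 and
1/4, give 24 features. The four feature *families* (Hessian, Laplacian,
standard deviation, circular standard deviation) with a 7-pixel kernel and
three scales are fixed by the procedure; the exact per-scale decomposition
into 8 planes is our design: it contains all four families, reaches 24
exactly, and keeps the raw intensity plane so the spectral-category signal
of the cluster image survives into the classifier.

Numerical choices:

- Derivatives are Gaussian-derivative filters with σ = kernel/4, normalized
  on the discrete grid so that the responses to 1, x and x² are exactly
  0/1/2. Smoothing-based derivatives are the standard choice for texture
  features when only a kernel size is specified.
- Borders are symmetric (reflect) padded everywhere.
- The circular standard deviation is `sqrt(-2 ln R)` of the gradient
  orientations over the 7×7 window, magnitude-weighted, in the doubled-angle
  convention because orientations of edges are axial quantities. `R` is
  floored at 10^-6 (capping the plane at ≈ 5.26) and windows with zero total
  gradient magnitude — including gradients at floating-noise level relative
  to the image scale — yield 0.
- Downscaling is block averaging (factors 1/2 and 1/4 are block-exact for
  the image sizes used; other sizes are edge-padded to a multiple), and
  planes are upsampled back by nearest neighbor, which is deterministic and
  shape-exact.

## The random forest

A forest of 100 trees (depth ≤ 50) in which each node's rule is either a
single feature compared to a threshold or the **difference of two features**
compared to a threshold. The difference rule is an oblique split: a boundary
of the form f~i~ − f~j~ = t takes one node, where axis-aligned trees need a
staircase of many splits (the package's tests construct such a case and
verify the gap).

Training grows each tree from the root: at every node ~400 candidate rules
are proposed (type uniform; feature indices uniform, distinct for
difference rules; threshold uniform between the min and max of the rule's
expression over the node's samples), and the candidate with the largest
entropy reduction — parent entropy minus the size-weighted child entropies,
in bits — is kept. Growth stops on purity, the depth limit, a degenerate
node, or when no candidate reduces entropy; leaves store the class
frequencies of the samples that reached them ("generation probabilities").
Prediction averages the leaf probabilities of all trees and returns the
argmax class, ties toward the lowest class code.

Where the procedure leaves freedom, the package fixes:

- **Candidate count exactly 400** per node (deterministic, not "around").
- **Bootstrap**: each tree receives its own stratified sample with
  replacement from the pooled training pixels, per-class allocation
  proportional to class frequency, capped at `per_tree_sample` (default
  100,000; full 2048² image sets pool ~10^7–10^8 pixels, so an uncapped
  bootstrap is impractical). Ignore-labeled and invalid pixels never enter.
- **Thresholds** are sampled from the node-local expression range; no
  global quantile scheme is implied by the procedure.
- `min_samples_leaf` defaults to 1 and is exposed.
- Tie-breaks everywhere go to the first proposed candidate / lowest class
  code, making results independent of evaluation order.
- Training and prediction run in C++ with a self-contained splitmix64 RNG
  seeded from the configuration, so identical seeds give byte-identical
  serialized models on any platform, independent of R's RNG state.

## Evaluation

Pixel-wise precision `TP/(TP+FP)`, recall `TP/(TP+FN)` (each 0 when the
denominator is 0) and `F_beta = (1+beta^2) PRE REC / (beta^2 PRE + REC)` at
β = 0.5 and 1 (F₁ = Dice), per class over the evaluable (non-ignored)
pixels.

Object-wise metrics use ground-truth objects only: each object is assigned
the plurality label of its pixels' predictions (ties to the lowest code) and
counts as correct when that label equals its true class. Object-wise recall
for class c divides correct true-c objects by all true-c objects; precision
divides them by all ground-truth objects whose plurality label is c. We use
ground-truth objects for the precision denominator because no instance
segmentation of the predictions exists — objects are only defined on the
truth. The external region has no objects and is excluded from object
metrics and from the three-class averages.

Leave-one-out cross-validation holds out one image per fold; the clustering
model and the forest are fitted on the remaining images only (the driver
asserts this structurally), the held-out image is clustered, featurized and
classified, and per-fold metrics are averaged as mean ± s.d. over folds (not
pooled over pixels).

## The synthetic scene generator

`generate_scene` emulates the structure of the real NSC images: elliptical
cell bodies with a two-zone subcellular spectral structure — a
high-intensity center spectrum (`N_high` / `G_high`) and a low-intensity
edge band (`N_low` / `G_low`) — widened random-walk processes attached to
the bodies sharing one spectrum regardless of parent type (mirroring the
single combined process class), an external region near transmittance 1, a
smooth low-order-polynomial multiplicative illumination field, a dark
offset, and additive Gaussian sensor noise in counts (clipped at 0;
the simplest model that exercises both the flat-field correction and the
classifier's noise robustness). The rendered frames are
`O = round(signature × illum × (flat − dark) + dark + noise)`,
`F = round(dark + illum × (flat − dark) + noise)` and
`D = round(dark + noise)`; the flat frame carries the additive dark offset,
as a real sensor's would, so flat-field correction cancels the illumination
field exactly.

Default conditions: 25 bands (450–690 nm); illumination amplitude 10%
peak-to-peak (within the 3.5–14.1% non-uniformity observed on the
instrument); noise s.d. 2% of the dynamic range; dark level 100 and flat
level 3100 counts (absolute count scales are free parameters — the
instrument reports arbitrary units — only their ratio to the noise matters);
a few neurons and glia per 256² field with 10–18 px body semi-axes, 3 px
edge bands and 2–3 px wide processes. The signature bank keeps the
qualitative ordering of the real major spectra: body centers brighter and
body edges darker than the external region, and the glial center spectrum
rising toward long wavelengths relative to the process spectrum.

What the generator does **not** emulate: organelle-level texture beyond the
two-zone body structure, fluorescence channels or ambiguous phenotypes
(beyond an optional injected ignore rectangle), chromatic aberration,
spatially correlated noise, and out-of-focus light. Consequently the
synthetic classes are better separated than real ones: passing tests show
the pipeline's correctness and its behavior under noise, not field
performance on real cultures. The evaluation run used by
`scripts/acceptance.R` (6 scenes of 256², 50 trees of depth ≤ 25,
50,000-pixel bootstraps) is a scaled-down surrogate of the real study
(19 images of 2048², 100 trees of depth ≤ 50); the problem sizes were chosen
so a full leave-one-out run stays in the minutes range on one CPU while
every stage still operates well above its small-sample regime.

## Optics quality metrics

The lateral two-point resolution under partially coherent illumination is
`R = A(sigma) * lambda / NA_obj`, with the coherence ratio
`sigma = NA_ill / NA_obj` and `A(sigma)` interpolated from the tabulated
two-point criterion curve: constant 0.82 on the near-coherent plateau
(σ ≤ 0.2) and decreasing toward the incoherent (Rayleigh, 0.61) limit. With
the default optics (NA 0.45 objective — the manufacturer value for the lens
model, not printed in the imaging protocol — and NA 0.063 illumination,
σ ≈ 0.14) this gives 0.820 / 1.002 / 1.184 µm at 450 / 550 / 650 nm.

Temporal fluctuation reports, per tolerance, the fraction of pixels whose
maximum absolute deviation from their temporal mean stays within the
tolerance, as a percent of the global mean intensity at that wavelength
(the normalizer "mean intensity at each wavelength" is read as the global
spatial-temporal mean). Spatial non-uniformity is the peak-to-peak range
over the field of view after 5×5 median smoothing (to suppress shot noise),
as a percent of the mean — the statistic behind the instrument's published
non-uniformity percentages is not defined, so this is one consistent
reading and those values are not reproduced quantitatively.

## Known limitations

- The cluster-image display mapping and the 8-plane feature decomposition
  are reasoned choices among several consistent readings (see above); both
  are configurable.
- Object-wise precision is defined on ground-truth objects, so it is not
  comparable to instance-segmentation precision.
- The generator's spectra are piecewise-linear idealizations; no claim is
  made that absolute classifier scores transfer to real acquisitions.
- k-means and forest training are exact re-implementations of the described
  procedures, not bindings to external ML libraries; speed comes from C++
  hot paths, and extremely large `k` or tree counts will scale linearly.
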