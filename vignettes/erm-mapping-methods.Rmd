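---
title: "Methods: en-face mapping of epiretinal membrane presence in OCT volumes"
author: "ermmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: en-face mapping of epiretinal membrane presence in OCT volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The epiretinal membrane (ERM) is a fibrocellular tissue that forms over the
inner retinal surface. In an OCT B-scan it appears as a thin hyper-reflective
band attached to — or floating a few pixels above — the inner limiting
membrane (ILM). Reading an entire macular cube (tens to hundreds of B-scans)
slice by slice is tedious, so `ermmap` automates the reading and condenses it
into a single en-face map: one row per B-scan, one column per lateral
position, white where ERM is detected.

The pipeline is: snake segmentation of the ILM in every B-scan; a 452-value
descriptor of a rectangular neighbourhood around every ILM point; SURF
(Spatial Uniform ReliefF) relevance ranking of those features; training and
cross-validated comparison of five classifier configurations (random forest,
RBF-SVM, and kNN with k = 2, 6, 8) over a grid of feature counts; row-wise
assembly of the per-slice predictions into the en-face map; and a
morphological clean-up (small-component removal, then binary closing) whose
parameters are chosen by exhaustive grid search maximizing mean Dice.

## The synthetic phantom

No public ERM-annotated OCT volume collection exists, so the package carries
a generator of synthetic volumes with exact per-pixel ground truth
(`phantomSpec()` / `generatePhantom()`). A phantom emulates the properties
the detector actually exploits:

* a dark vitreous cavity above a single-valued bright surface;
* ILM depth varying smoothly: a parabolic foveal dip
  (`ilmCurvatureAmp`, default 12 px) plus a per-slice low-frequency
  sinusoidal undulation (`ilmWobbleAmp`, default 3 px);
* a brighter tissue band below the surface (`retinaThickness`, 60 px);
* an ERM band of `ermThickness` (2 px) rendered at `ermLevel` (200) over
  contiguous lateral extents, attached (`detachPx = 0`) or slightly
  elevated;
* multiplicative speckle, `pixel * (1 + N(0, sigma))` clipped to 8 bits,
  with `speckleSigma = 0.1` as the default stress level.

Mean 8-bit levels are vitreous 25 < tissue 120 < ERM 200, mirroring the
hyper-reflectivity ordering of real scans. The defaults define the reduced
study conditions used throughout the tests and the acceptance script:
volumes of 32 slices at 160 x 128 px, 5 training and 5 test volumes with
ERM plus 3 without, 2 000 balanced training samples, a 400-window PCA
basis. These sizes keep a complete study tractable on a single CPU while
leaving every stage statistically meaningful.

What the phantom does **not** emulate: physically realistic speckle
statistics (real OCT speckle is neither Gaussian nor pixel-independent),
vessel shadowing, motion artifacts, intensity roll-off with depth, layered
sub-retinal anatomy, or pathologies that deform the surface (edema,
detachment). Passing the synthetic study therefore demonstrates that the
pipeline's machinery is correct and self-consistent — not that its accuracy
transfers to clinical scans, whose variability is far richer.

## ILM segmentation

The ILM is recovered with a discrete Kass-style active contour restricted
to vertical movement: one row value per column, which matches the geometry
of the problem (the ILM is a single-valued surface in a B-scan, and the
feature stage needs exactly one ROI point per column). The energy is

\[ E(v) = \sum_c \tfrac{\alpha}{2}(v_{c+1}-v_c)^2
        + \tfrac{\beta}{2}(v_{c+1}-2v_c+v_{c-1})^2
        - w_e\, G(v_c, c) - w_p\, v_c \]

with \(G\) the per-column normalized gradient magnitude of the
Gaussian-smoothed scan. Two choices deserve explanation:

* **Downward pressure** \(w_p\) (default 2.5): a contour initialized at the
  top of the image sits in the featureless vitreous where the edge force is
  zero; a small constant pressure carries it down until the
  vitreous-to-retina edge captures it. The capture condition is
  \(w_e |\partial G/\partial y| > w_p\), so the defaults
  (\(w_e = 50\)) hold the contour at any column whose normalized edge slope
  exceeds 0.05.
* **Per-column normalization of the edge map** (plus one extra smoothing
  pass of the gradient magnitude): A-scans differ in contrast, and a single
  global normalization would let the contour punch through weaker parts of
  the surface while being held by stronger ones.

Steps are semi-implicit in the internal terms
(\(v \leftarrow (I+\gamma A)^{-1}(v + \gamma f_\text{ext})\)) with
backtracking step halving, so the discrete energy is non-increasing by
construction — the property the tests assert. Iteration stops when the mean
per-column movement falls below `convTol` (0.05 px equivalent; default
0.02) or after `maxIters` (600). Defaults \(\alpha = 0.1\), \(\beta = 1\),
\(\gamma = 0.2\), smoothing \(\sigma = 2\) px were chosen on phantom
oracles and are all exposed in the run configuration. A constant image has
no edge anywhere and raises an error rather than returning an arbitrary
contour. Where an ERM band is attached to the surface the contour rides on
the band's top edge; that is intended — the feature window is meant to be
centered on the visible surface.

## The 452-feature descriptor

Each eligible ILM point is described by a vertical rectangle of width
`subSide` (15 px) and height `5 * subSide`, centered laterally on the point
and vertically on the ILM row, partitioned into five stacked square
sub-windows: two above the surface (vitreous/ERM space), one straddling it,
two below (retina). Points closer to an image border than the window
half-extent are excluded from sampling and predicted as background.

The per-category composition is fixed and asserted at construction
(10 + 16 + 160 + 64 + 28 + 75 + 13 + 5 + 81 = 452):

| block | count | definition |
|---|---|---|
| PCA | 10 | projection of the vectorized, mean-centered window onto the first 10 principal components of training windows (SVD; component signs fixed by largest loading) |
| GLCM | 16 | Haralick contrast, correlation, energy, homogeneity at distance 1 for 0/45/90/135 degrees on a 16-level quantized window, symmetrized |
| Gabor | 160 | bank of 4 wavelengths (2, 3, 5, 8 px) x 8 orientations; mean response magnitude (complex modulus, DC-free) within each of the 5 sub-windows |
| LBP | 64 | full 64-bin normalized histogram of local binary pattern codes, P = 6 neighbors, R = 1, bilinear interpolation |
| Laws | 28 | 5x5 kernels from {L5,E5,S5,W5,R5}; 14 symmetric-pair absolute-response maps (L5L5 dropped); mean and sd of each over the window |
| window | 75 | per sub-window: mean, sd, min, max, median, range, skewness, kurtosis, entropy, energy, and a 5-bin normalized histogram |
| intensity global | 13 | mean, median, sd, variance, min, max, range, skewness, kurtosis, entropy, energy, 25th and 75th percentile of the full rectangle |
| GLIH | 5 | 5-bin normalized gray-level histogram of the full rectangle |
| HOG | 81 | 3x3 spatial cells x 9 unsigned orientation bins, magnitude-weighted, single-block L2 normalization |

Numerical conventions that keep every value finite: skewness and kurtosis
are defined as 0 on (near-)constant inputs; GLCM correlation is 0 when the
marginal variance vanishes; the HOG block is all-zero on gradient-free
windows; histogram bins are fixed absolute partitions of [0, 1] so the
features remain deliberately intensity-sensitive (the ERM is
hyper-reflective — rescaling invariance is *not* wanted). Entropy and
energy are computed from the 5-bin histogram within sub-windows and from a
16-bin histogram for the global block.

Window size is not dictated by the data source, so `subSide = 15` was
chosen to make a sub-window comparable to the ERM thickness scale; it is a
run-configuration parameter. The PCA basis is fit once, globally, on
windows sampled from the training volumes and travels with the trained
model. Filter responses (Gabor, Laws, LBP codes, gradients) are computed
once per B-scan through a batched FFT correlation and the per-point
features are cheap window aggregations of those maps.

## SURF feature ranking

SURF replaces ReliefF's neighbor count k with a global threshold: the mean
Euclidean distance over all unordered instance pairs, computed on features
min-max scaled to [0, 1]. Every instance within the threshold is a
neighbor; miss neighbors add the per-feature absolute difference (weighted
by 1/(n m_i)), hit neighbors subtract it (1/(n h_i)). All instances are
used — no sampling — so the weights are deterministic and invariant to
sample order, and the implementation is checked against an independent
brute-force reference to 1e-10. Ranking ties break by ascending feature
index for reproducibility. The distance metric and the pre-scaling are this
package's choices (the standard ReliefF conventions).

## Classifiers and the selection protocol

Five configurations are compared: random forest (100 trees), RBF-SVM, and
kNN with k = 2, 6, 8 (Euclidean distance on the min-max scaled features,
unweighted votes, vote ties broken toward the background class — a
conservative choice that matters at even k). Training data are balanced
exactly (ceiling(n/2) positives). Evaluation is stratified 10-fold
cross-validation; accuracy is the model-selection metric.

Two protocol decisions are worth flagging:

* The SURF ranking is computed once on the full training sample and applied
  inside cross-validation as a fixed index set. This mirrors the
  feature-count-sweep protocol but carries a known optimistic bias
  (selection sees the held-out folds); it affects model *selection*, not
  the held-out test volumes on which the maps are evaluated.
* SVM hyper-parameters (cost in {0.1, 1, 10, 100}, gamma = 1/k times
  {0.1, 1, 10}) are grid-searched once, at a fixed feature count of 100,
  before the sweep, then held fixed — the "baseline first, sweep second"
  ordering; re-tuning inside every fold of every sweep cell would multiply
  the fit count roughly twelvefold without changing the protocol's
  conclusions.

The sweep evaluates k in {20, 40, ..., 200}; the per-classifier optimum can
optionally be refined by unit steps around the coarse argmax
(`selector$refine`), with ties toward fewer features.

## Map reconstruction and refinement

Row i of the en-face map is the prediction vector of slice i. Refinement
follows the stated operation order: connected-component area filtering
first (components smaller than `minArea` pixels are removed), then binary
closing with a disk of radius `closingRadius`. Component connectivity
defaults to 8 so diagonally adjacent detections across consecutive B-scans
count as one region; it is configurable to 4. The closing is computed as if
the map were embedded in an infinite background (zero padding wider than
the structuring element), which makes the whole refinement idempotent. The
en-face grid treats slice spacing and lateral pixel pitch as equal —
anisotropy correction is out of scope.

Both parameters are chosen by exhaustive search over
minArea in {0, 10, 25, 50, 100, 200} x closingRadius in
{0, 1, 2, 3, 5, 7}, maximizing mean Dice over the complete set of
ERM-positive study volumes — the post-processing stage is evaluated
in-sample, an explicit protocol property of this stage (the point
classifier itself never sees the test volumes). The grid contains the
identity (0, 0), so the chosen configuration can never be worse than no
refinement on the optimized set; when the raw maps are already clean the
search simply returns the identity. Ties prefer
smaller minArea, then smaller radius. Volumes whose ground truth contains
no positives contribute no Dice; if *all* supplied truths are empty the
optimizer refuses and points to specificity-based selection.

## Evaluation

Confusion counts are tallied at en-face map-pixel level, per volume, before
and after refinement; sensitivity, specificity, Dice and Jaccard follow the
standard formulas. For ERM-free volumes TP + FN = 0 and sensitivity, Dice
and Jaccard are reported as undefined (NA) rather than 0 — only specificity
is meaningful there — and aggregation (mean, sample n-1 sd across volumes)
skips undefined entries. A slice-level reading (row-wise any-positive) can
be derived from the maps but the pixel level is the default, matching the
per-map confusion framing the maps are built for. The identity
J = D/(2 - D) links the two overlap coefficients for any single confusion
matrix and is used as a cross-check in the tests.

## Known limitations

* Synthetic validation only: the study demonstrates internal correctness,
  not clinical performance (see the phantom section).
* The snake assumes a single-valued, top-visible surface; full retinal
  detachment or vitreous debris above the ILM would defeat it.
* The global-ranking CV bias noted above.
* Feature extraction treats each B-scan independently; only the
  post-processing stage uses inter-slice context.
* The refinement structuring element is isotropic in map pixels even
  though slice spacing usually exceeds lateral pitch in real cubes.
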