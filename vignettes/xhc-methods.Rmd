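---
title: "Extreme hierarchical clustering of hyperspectral cubes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extreme hierarchical clustering of hyperspectral cubes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xhclust)
```

## The problem

A hyperspectral push-broom camera delivers, for every pixel of a scene, a
reflectance spectrum over a few hundred narrow wavebands. For biological
specimens such as in-vitro wound models there is usually no labelled
training data, so segmentation must be unsupervised; and a single
acquisition can hold millions of signatures, so the clustering must be
cheap. `xhclust` implements a divisive decomposition — extreme
hierarchical clustering (XHC) — whose per-node cost is linear in the node
size, followed by a k-means consolidation of the tree's leaves and a
nearest-representative labelling of all pixels.

## Preprocessing model

**Calibration.** Raw counts become reflectance via
$R = (\mathrm{raw} - \mathrm{dark}) / (\mathrm{white} - \mathrm{dark})$
per pixel and band, against a white reference standard and a
closed-shutter dark-current measurement. References may be per-band
vectors or spatially resolved cubes; the arithmetic is identical, and the
result is invariant under any affine rescaling of the sensor response
(gain and offset cancel). Bands where white − dark is not strictly
positive are unusable and raise an error naming the band. Reflectance
above 1 is *kept* at this stage: it is diagnostic of overexposure and is
handled by masking, not clamping.

**Smoothing.** Each spectrum is smoothed by a Savitzky–Golay filter:
a sliding least-squares polynomial fit of degree 5 over 7 supporting
points on each side (15-band window). These defaults suit reflectance
sampled at a few nm; the filter reproduces any polynomial up to degree 5
exactly, so genuine broad spectral structure is untouched while
band-to-band noise is averaged out. At the spectrum ends the fit window
shrinks to the available points at the same polynomial order, rather than
padding with invented data; interior bands are identical to the classical
convolution filter, which the test suite verifies against
`signal::sgolayfilt` and against a direct per-window regression oracle.

**Cropping.** Only bands in the closed interval 450–790 nm are retained
by default; detector response at the spectral extremes is noisy. The
pipeline order is fixed as *smooth, then crop, then mask*: smoothing
first lets interior bands near 450 and 790 nm use their full windows, and
masking must see the final band set because both mask rules are reductions
over retained bands. Smoothing and cropping do not commute near the crop
boundary, so the order is part of the contract and regression-tested.

**Masking.** A pixel is excluded as *overexposed* iff its maximum
reflectance over retained bands is strictly greater than 1 (specular
fluid), and as *background* iff its mean reflectance falls below 0.05
(tissue on a low-reflectance dish is far brighter than the dish). The
background threshold is a heuristic for intensity-separable backgrounds;
an externally supplied mask overrides it for scenes where background and
specimen overlap in brightness. Mask union is monotone: combining masks
never unmasks a pixel, and the first rule to fire keeps the reason code.

## The clustering

Signatures are the columns of $X \in \mathbb{R}^{m\times n}$. Each tree
node handles a subset of columns:

1. **Pivots.** Pick a start column uniformly at random (seeded); let $b$
   be the farthest column from it and $a$ the farthest column from $b$,
   under the Euclidean distance. The pivots approximate the subset's two
   most extreme points, so the induced axis spans the widest spread of the
   node. Farthest-point ties resolve to the lowest column index.
2. **Projection.** Every member $x$ is mapped to
   $\mathrm{Proj}(x) = \bigl(d(a,x) + d(a,b) - d(b,x)\bigr) / \bigl(2\,d(a,b)\bigr)$,
   the package's default (`as_printed`). This unsquared form maps $a$ to
   0, $b$ to 1 and all points into $[0,1]$ by the triangle inequality.
   The classical FastMap embedding uses squared distances,
   $\mathrm{Proj}(x) = \bigl(d(a,x)^2 + d(a,b)^2 - d(b,x)^2\bigr) / \bigl(2\,d(a,b)\bigr)$,
   available as variant `law_of_cosines`. The two variants order points
   differently in general and therefore produce different thresholds;
   since both yield valid 1-D embeddings the choice is exposed as a
   parameter rather than hidden, with `as_printed` as the default.
3. **Split.** With projections sorted, the split index minimises
   $c_i = \frac1i\sum_{j\le i}(s_j-\mu_1)^2 + \frac1{n-i}\sum_{j>i}(s_j-\mu_2)^2$ —
   the sum of the two within-side *mean* squared deviations, each side
   normalised by its own count. Note this is not the pooled
   (size-weighted) within variance; the per-side normalisation slightly
   favours balanced cuts with a pure small side, which suits archetype
   hunting. Ties go to the smallest index. The node rule is
   $\mathrm{Proj}(x) \le \theta$, $\theta = (s_i + s_{i+1})/2$. The
   implementation uses prefix sums ($O(n)$ after sorting); the test suite
   holds it equal to an exhaustive direct-summation evaluator at every
   split index.
4. **Stopping.** A node becomes a leaf when it holds fewer than
   `2 * min_leaf` members (so no child can fall below a sensible size),
   when `max_depth` is reached (root at depth 0, default 10), or when it
   is degenerate — all members identical, all projections equal, or a
   threshold that fails to separate the members. Each leaf stores its
   member indices and mean spectrum.

**Pruning.** Lloyd k-means (iteration cap 1000) on the leaf means yields
the k representatives. Initialisation is a seeded farthest-point
(maximin) sweep: the first centre is a seeded uniform draw, each further
centre the point farthest from the chosen set. Leaf means are archetypal
summaries, typically few and well spread, and maximin seeding guarantees
that separated groups of leaf means each receive a centre — a random
(Forgy) draw can easily miss a small group when cluster sizes are very
unbalanced, and Lloyd iterations cannot recover across well-separated
modes. An emptied centroid is re-seeded on the worst-fitted point, so k
clusters stay alive. The same implementation serves as the flat k-means
baseline; a test pins its fixed points to `stats::kmeans` (Lloyd) started
from the same centres.

**Determinism and ordering.** The entire fit is a pure function of
(data, parameters, seed). Before seeding, the leaf-mean columns are put
into a canonical order (by mean reflectance, then lexicographically by
band), and the final representatives are canonicalised the same way.
Consequently the model is *exactly* invariant to the order of tree leaves
and of data subsets, and cluster ids are stable across reruns — the
property that makes per-cluster time series comparable between runs. In
the parallel variant (one tree per image, leaf means pooled, one k-means
on the pool), every subset tree is grown from the master seed, so a
subset's tree does not depend on its position in the list; with a single
subset the parallel path reduces bit-for-bit to the serial one.

**Assignment.** Each signature takes the label of its nearest
representative (Euclidean), ties to the lowest id. Assignment is
independent of how the model was trained, so a model learned on early
time points (the manifest marks training images) can label all images.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `polyorder`, `half_window` | 5, 7 | –, bands | smoothing fit order and half-window |
| `lo_nm`, `hi_nm` | 450, 790 | nm | retained spectral interval (closed) |
| `background_threshold` | 0.05 | reflectance | mean below ⇒ background |
| `overexposure_threshold` | 1.0 | reflectance | max strictly above ⇒ overexposed |
| `max_depth` | 10 | levels | tree depth cap |
| `min_leaf` | 100 | signatures | split only nodes ≥ 2·min_leaf |
| `k` | 7 | clusters | number of final representatives |
| `max_iters` | 1000 | iterations | k-means cap (pruning and baseline) |
| `seed` | 0 | – | all start-point and seeding draws |

`min_leaf` should scale with the image: 100 suits megapixel acquisitions
(keeping leaf counts tractable while resolving ~7 tissue classes); the
64×64 synthetic scenes used throughout the tests hold only ~2400 tissue
pixels, so tests and the acceptance script use `min_leaf = 50` (and 25
for half-size subsets) to give the pruning step enough leaves.

## The synthetic scene generator

Real wound-model cubes are large and not shipped, so validation runs on
generated scenes with exact ground truth. A scene is piecewise constant:
a dark background (reflectance 0.01), a concentric tissue disc — outer
periphery, wound-margin annulus, central wound bed, one endmember each —
plus `n_overexposed` fluid pixels with per-band values in 1.05–1.5.
Endmembers are sums of 2–4 Gaussian bumps, peak ≤ 0.9, band-to-band
change ≤ 0.045, mean ≥ 0.15, pairwise Euclidean separation ≥ 1 by
construction; per-pixel noise is iid Gaussian (sd 0.01 by default,
clipped at 0). The default geometry is 64×64 pixels × 125 bands
(450–790 nm at 2.73 nm steps), small enough that the full test suite and
the acceptance script run in minutes on one CPU while preserving the
structure that matters (three separated classes, unbalanced sizes, dark
background, overexposure). A timecourse generator shrinks the wound-bed
radius over "days" for control series (factor $1 - 0.08\,\mathrm{day}$)
and keeps it constant for treated series, exercising training-on-early-days
and ROI quantification.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: spectral gradients within a tissue region,
spatially correlated or signal-dependent sensor noise, chromophore
absorption structure, scattering, illumination inhomogeneity, or
mixed-pixel boundaries. Recovery at ARI ≥ 0.95 on these scenes validates
the machinery (projection, splitting, pruning, assignment, masking,
plumbing), not clinical segmentation quality.

## Numerical choices and degenerate inputs

- Distances are computed vectorised per node; negative rounding inside
  `sqrt` is clamped at 0.
- `best_split` evaluates all n−1 candidate indices by prefix sums in
  double precision; cost ties resolve to the smallest index for
  determinism.
- A constant node, a constant projection list, or a threshold that fails
  to separate members each turn the node into a leaf rather than erroring.
- ENVI I/O is restricted to the dialect the surrounding tooling emits:
  interleaves bil/bip/bsq, float32 and uint16, little endian, wavelengths
  in nm. float32 payloads round-trip bit-exactly; header/payload
  mismatches raise corrupt-file errors rather than truncating.
- Pixel coordinates are 1-based `(row, col)`, origin top-left, matrix
  columns in row-major pixel order — one fixed convention everywhere.

## Scope and limitations

The per-node projection uses two pivots only; highly non-convex cluster
shapes in spectral space can straddle a split (k-means pruning partially
repairs this). The background rule is a brightness threshold and will
misfire when specimen and background have similar albedo — supply an
explicit mask then. Wall-clock performance claims, supervised
classification, spectral unmixing and statistical comparison across
conditions are out of scope; the package stops at label maps and
per-cluster counts.
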