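# xhclust

Unsupervised segmentation of hyperspectral image cubes by **extreme
hierarchical clustering (XHC)** — a divisive decomposition tree driven by
FastMap projections onto the data's most extreme (archetypal) spectra —
with the full preprocessing chain around it: ENVI I/O, white/dark
reflectance calibration, Savitzky–Golay smoothing, band cropping,
background/overexposure masking, and per-cluster quantification inside
circular regions of interest. It targets workflows such as non-invasive
monitoring of in-vitro wound models, where each pixel of a push-broom
acquisition carries a reflectance spectrum and no labelled training data
exist, but it applies to any hyperspectral cube.

## The method

A cube is flattened to a dense matrix **X** ∈ ℝ^(m×n): columns are the
spectra ("signatures") of the unmasked pixels, rows the m wavelengths.
XHC then proceeds in three steps.

**1. Tree decomposition.** At each node, two *pivot* signatures are found
by a farthest-point walk — pick any point, take the farthest point **b**
from it, then the farthest point **a** from **b** — using the Euclidean
distance `Dist(a,b) = sqrt(Σᵢ (aᵢ−bᵢ)²)`. Every member **x** is projected
onto the pivot axis,

    Proj(x) = (Dist(a,x) + Dist(a,b) − Dist(b,x)) / (2 · Dist(a,b)),

which places **a** at 0, **b** at 1 and, by the triangle inequality, every
point in [0, 1] (a squared-distance law-of-cosines variant is also
available). The sorted projections s₁ ≤ … ≤ sₙ are split at the index i
minimising the sum of within-side mean squared deviations,

    cᵢ = (1/i) Σ_{j≤i} (sⱼ − μ₁)² + (1/(n−i)) Σ_{j>i} (sⱼ − μ₂)²,

and the node rule becomes `Proj(x) ≤ θ` with `θ = (sᵢ + sᵢ₊₁)/2`.
Recursion stops at a minimum leaf size or a maximum depth (default 10).
Because the pivots are extreme points, splits follow the data's
archetypes rather than its bulk — small but spectrally distinct regions
(e.g. a wound bed) separate early.

**2. Post-pruning.** Lloyd k-means (cap 1000 iterations) on the leaf-mean
spectra reduces the leaves to k representatives (default k = 7). For
massive data the tree step parallelises trivially: one tree per image,
leaf means pooled, one k-means on the pool.

**3. Assignment.** Every signature of every image is labelled with its
nearest representative.

## Worked example

A ground-truthed synthetic wound scene (64×64 pixels, 125 bands over
450–790 nm: dark dish background, tissue disc with periphery / margin /
wound-bed endmembers, 30 overexposed fluid pixels):

```r
library(xhclust)

scene <- make_wound_cube(scene_spec(seed = 1))
pp    <- preprocess_cube(scene$cube)         # smooth -> crop -> mask
pp$mask
#> pixel_mask: 64 x 64, 1654 excluded (background: 1624, overexposed: 30)

X <- cube_to_matrix(pp$cube, pp$mask)
X
#> spectral_matrix: 125 bands x 2442 signatures

model <- xhc_fit(X, k = 3, min_leaf = 50, seed = 1)
model
#> xhc_model: k = 3 representatives over 125 bands (from 46 leaves)

labels <- assign_clusters(X, model)
map    <- matrix_to_map(labels, X$pixel_index, c(64, 64))
quantify_clusters(map, circular_roi_mask(c(64, 64), diameter_px = 44))
#>   cluster pixels
#> 1       1    593
#> 2       2    710
#> 3       3    205
```

The mask recovers exactly the 30 constructed fluid pixels (reflectance
beyond 1) and the dish background; the three clusters recover the three
tissue regions perfectly here (adjusted Rand index 1 against the
generator's labels, computed with `mclust::adjustedRandIndex`). The ROI
counts are the per-cluster pixel numbers inside a centred 44-px disc —
the quantity tracked over days to follow wound closure (cluster 3 is the
wound bed, 205 px at day 0 geometry).

Batch runs go through the CLI (`inst/cli/xhc.R`): `synth`, `calibrate`,
`preprocess`, `cluster`, `assign`, `quantify`, `render`, e.g.

```sh
Rscript inst/cli/xhc.R synth   --out-dir scenes --seed 4 --days 0,5,10
Rscript inst/cli/xhc.R cluster --manifest scenes/manifest.yaml --out-dir run \
                               --k 3 --min-leaf 50 --roi-diameter 44
```

which writes `model.json`, a label map per image, `counts.csv`
(image, day, condition, cluster, pixel count) and a JSON run log.

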