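---
title: "corncloud: models, parameters and design choices"
author: "corncloud authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{corncloud: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(corncloud)
```

This vignette documents the scientific content of the package: the models
and procedures it implements, the parameters that matter and why their
defaults are what they are, what the synthetic data generator does and
does not emulate, and the numerical decisions taken where the design was
genuinely open. It states no empirical result beyond what the test suite
and `scripts/acceptance.R` themselves compute.

## The problem

Maize seedlings germinated in a cultivation tray are reconstructed
photogrammetrically as a point cloud: tray and soil, plus a handful of
thin-structured plants. Extracting per-plant traits requires separating
seedling points from background, splitting the seedling points into
individual plants, removing the arbitrary orientation and scale of the
reconstruction, and only then measuring. Each stage is a module with its
own contract, so each can be validated in isolation against constructions
whose answer is known.

## Semantic segmentation network

The segmenter is a hierarchical point network. The encoder applies three
cascaded set-abstraction (SA) levels; each level samples centroids by
farthest-point sampling, groups neighbours at two radii (multi-scale
grouping), lifts each group through a shared MLP, and max-pools the group
into a centroid feature. Between the MLP and the pooling sits a CBAM
block adapted to point sets: channel attention pools the group's features
over points (average and max), passes both through a shared
two-layer bottleneck MLP, sums and applies a sigmoid, giving one weight
per channel; spatial attention then compresses each point's channels to
an (avg, max) pair, maps it through a shared 1-point convolution (a
linear map to one channel) and a sigmoid, giving one weight per point.
Both maps are bounded in (0, 1) by construction, and with all-zero
weights each reduces exactly to a 0.5 rescaling — a contract the tests
pin down. The decoder mirrors the encoder with three feature-propagation
levels (inverse-squared-distance interpolation from the 3 nearest coarse
points, skip concatenation, shared MLP), and a point-wise head produces
two-class logits.

Choices worth recording:

- **Architecture defaults.** The full preset follows the public
  multi-scale-grouping segmentation configuration (npoint 4096, SA
  centroid counts 1024/256/64, radii 0.05–0.4 of the normalized scale,
  neighbour caps 16/32); the small preset is the same network at npoint
  1024 with halved widths, which is what the tests and the acceptance
  script use — the synthetic task is comfortably learnable at that size
  on one CPU core. Both are plain `netConfig()` values; nothing is
  hard-wired.
- **Input normalization.** Each cloud (or chunk) is centred and scaled
  into the unit sphere before the network; features are the normalized
  coordinates concatenated with the surface normals (6 channels). The
  grouping radii presume this normalization. Labels, not coordinates,
  are returned, so the transform needs no inverse.
- **No batch normalization.** The MLPs are linear + ReLU only. At these
  problem sizes training is stable without it, and the omission keeps
  the autodiff surface small. The tape implements exactly the operations
  the network needs and is validated end-to-end against central finite
  differences.
- **Loss.** The classification term is mean binary cross-entropy over
  points with probabilities clamped to [1e-7, 1 − 1e-7]; class weights
  are inverse-frequency, normalized to mean 1, so the minority seedling
  class carries proportionally more gradient. The optional regression
  term is a plain L1 sum over supplied (t, t̄) pairs with weight λ.
  λ defaults to 0: pure per-point segmentation provides no box pairs,
  and the hook exists for users who have them.
- **Training.** Adam at learning rate 5e-4 with weight decay 1e-4,
  batch size 24 (gradients accumulated over the batch, one cloud per
  forward pass), up to 100 epochs, best-validation-accuracy state
  retained. One integer seed drives initialization, resampling and data
  order; two runs with the same configuration produce identical logs.
- **Determinism and equivariance.** Farthest-point sampling starts from
  the point farthest from the centroid, grouping orders neighbours by
  distance, and pooling is max — so eval-mode inference is deterministic
  and permutation-equivariant (the tests check equality to 1e-5 under
  point reordering).
- **Full-cloud inference.** `predictCloud()` covers the cloud with a
  random partition into npoint-sized chunks (the last chunk padded by
  repetition); points covered more than once take a probability-summed
  vote.

## Instance separation: CornDBSCAN

DBSCAN with `minpts = 3` and a data-driven radius: each point's distance
to its 55th nearest neighbour (self excluded — "the most distant
neighbour within the k-nearest set") is a local density indicator, and
their mean over the cloud is the eps. The estimate is exercised against
an exhaustive pairwise-distance oracle in the tests, including the
closed-form collinear configuration (56 unit-spaced points give
eps = 41.5) and homogeneity under coordinate scaling.

Degenerate inputs are handled by the smallest sane generalization of the
formula: clouds with at most 55 points reduce k to N−1 with a warning;
clouds below minpts, or with eps = 0 (all points coincident), are labeled
entirely as noise. Clusters are renumbered 0..K−1 by decreasing size.
Distances are Euclidean in the coordinates as given — eps is estimated on
the same scale it is applied to, so no pre-normalization is wanted. The
eps estimate runs on the points being clustered (the semantic-1 subset),
since that is where the density assumption lives.

Matching predicted clusters to ground-truth plants maximizes summed IoU
over one-to-one assignments (Hungarian algorithm, written in the package
and tested against exhaustive enumeration). IoU-maximal matching rather
than raw-overlap matching keeps the objective aligned with the instance
IoU reported afterwards. Matches with zero overlap are dropped, so
spurious clusters count as false positives.

## Metrics

Semantic: Acc, Pre, Rec for the seedling class (the positive, minority
class), per-class IoU and their two-class mean (mIoU). Instance: per
matched pair, TP/FP/FN counts over points; pooled (micro-averaged)
precision, recall and F1; iIoU as the mean IoU over ground-truth
instances with unmatched instances contributing 0. Noise points belong to
no prediction: they are false negatives for their truth instance, never
false positives. Micro-averaging was chosen because tiny instances make
per-instance ratio averages unstable; the choice is isolated in one
function. Zero denominators yield 0 with the metric named in an
`"undefined"` attribute rather than NaN.

## Alignment, scaling, traits

- **Ground plane.** RANSAC over point triples, 1000 iterations, inlier
  threshold 1% of the cloud's bounding-box diagonal (the threshold must
  track scene scale; the iteration count is generous for desk-scale
  clouds). The consensus plane is refit by least squares and its normal
  oriented so the majority of non-inliers (the plants) lie on the
  positive side. Detection fails below a 30% inlier fraction.
- **Rotation.** The angle between the detected normal m and +z is
  `θ = cos⁻¹(m·n/|m||n|)`; the rotation is the standard Rodrigues matrix
  about the unit axis m×n. An exactly antiparallel normal is rotated
  180° about x by documented convention. Orthonormality and the exact
  mapping m → +z are asserted to 1e-9 over a thousand random draws.
- **Scale.** `k = L_real / L_virtual` with the 25 cm tray side as the
  default reference; lengths scale by k, areas by k², volumes by k³
  (asserted as exact homogeneity laws). When no reference measurement is
  supplied, the pipeline takes the larger horizontal extent of the
  detected ground-plane inliers after alignment.
- **Height** is the plant's own z-range — its lowest point is its soil
  contact — not the distance to the fitted plane, so a plant on a mound
  is not inflated.
- **Canopy width** is the horizontal AABB diagonal in the aligned frame.
  Note the AABB is taken after z-standardization; because the geodesic
  alignment introduces no azimuthal twist, the aligned frame's horizontal
  axes agree with the generator's, which is what makes the synthetic
  canopy oracle exact.
- **Voxel volume** uses 0.1 cm cubes anchored at the plant's AABB
  minimum corner, making the count exactly translation-covariant with
  the plant. A voxel is occupied iff it contains at least one point, so
  the measurement is of the sampled point set: sparse sampling
  underestimates the solid volume, and the manifest's nominal solid
  values are not comparable at low densities.
- **Surface area** comes from single-radius (0.2 cm) ball-pivoting
  reconstruction with triangle areas by Heron's formula. The C++
  implementation applies a deterministic sub-tolerance symbolic
  perturbation to break the cocircular degeneracies of gridded inputs
  (which otherwise admit two conflicting triangulations of each lattice
  square) and, when normals are available, keeps the pivot ball on the
  outward side of the surface so it cannot roll through an open boundary
  onto the back face. Areas are measured on the unperturbed coordinates.
  The flat-grid and sphere oracles bound the error well under the 10%
  the tests assert.

## The synthetic scene generator

A scene is a z = 0 tray square (default 25 cm, 1500 points) plus K
seedlings: a vertical stem (radial Gaussian spread, sd 0.075 cm) with
2–4 parabolic leaf ribbons attached between 30% and 70% of the stem
height, rising but staying below the stem tip, 600 points per plant,
plus additive Gaussian jitter (sd 0.05 cm). Defaults: heights U(8, 15) cm,
per-axis canopy extents U(2.5, 4) cm — young tray seedlings — placed by
rejection sampling with a guaranteed 2.5 cm edge-to-edge canopy
clearance; tilt U(5, 20)° about a random horizontal axis in the dataset
generator. These values were fixed once as the generator's study
conditions.

Ground truth is recorded from the realized (noisy, untilted) points —
the direct-scan oracle: height is the plant's z-range, canopy its
horizontal AABB diagonal; with zero noise these equal the designed values
exactly because the stem endpoints and one full-reach leaf point are
forced. Volume and area in the manifest are nominal analytic values of
the generating solids (stem cylinder plus ribbon laminae) and are
documented as approximate; the voxel and mesh measurements of a sparse
point sample are not expected to reach them. Tilt and the world-scale
factor are applied only after ground truth is recorded, so alignment and
scaling are genuinely tested.

Deliberate simplifications: the tilt axis is horizontal (a physical tray
tilt), which also guarantees the twist-free alignment the canopy oracle
needs; plants never touch (real trays have touching and occluding
seedlings — cluster-count recovery on these scenes says nothing about
that regime); there is no soil texture, no reconstruction artifacts, no
growth dynamics. Passing tests on synthetic scenes therefore validate
the machinery — label bookkeeping, estimator formulas, geometry — not
performance on real photogrammetric data.

## Problem sizes used in the tests

The suite and the acceptance script run at desk scale, chosen once:
network experiments at npoint 1024 (small preset) with 4-scene overfit
runs and a 40-scene split (28/4/8) trained with batch 8 and early stop at
99.5% validation accuracy; clustering recovery over 100 seeded scenes
with 2–6 plants; trait recovery over 50 tilted noisy scenes; the
augmentation count on 106 scenes at reduced point density (the 7× file
bookkeeping is density-independent); mesh oracles on a 21×21 grid patch
and a 20k-point sphere.

## Known limitations

- The network is CPU-bound R; at the full 4096-point preset and hundreds
  of clouds, training is slow. The architecture code is deliberately
  preset-parametric so the full configuration remains available.
- CornDBSCAN inherits DBSCAN's failure mode when inter-plant gaps fall
  below the estimated eps (touching canopies merge into one cluster);
  the adaptive eps helps across densities but cannot split contact.
- Ball-pivoting at a single radius leaves holes where local spacing
  exceeds the ball diameter; area is then a lower bound. A multi-radius
  cascade would mitigate this and is left as an explicit non-default.
- The fixed-eps DBSCAN baseline is retained (`dbscanCluster()`), but no
  other clustering baselines are provided.
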