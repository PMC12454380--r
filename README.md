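# corncloud

3D phenotyping of maize seedlings grown in cultivation trays, from
photogrammetric point clouds.

Tray-grown seedlings are routinely reconstructed as 3D point clouds
(e.g. from smartphone video via structure-from-motion). Turning such a
cloud into per-plant trait measurements requires four steps, all of which
this package implements:

1. **Semantic segmentation** — classify every point as *seedling* or
   *non-seedling* with a hierarchical point network (PointNet++-style set
   abstraction with multi-scale grouping and feature propagation) whose
   PointNet layers are augmented with CBAM attention:
   channel attention `Mc(F) = σ(MLP(AvgPool(F)) + MLP(MaxPool(F)))`
   followed by spatial attention
   `Ms(F₁) = σ(f([AvgPool(F₁); MaxPool(F₁)]))`, applied before the local
   max-pooling. Training minimizes a composite loss
   `L = Lcls + λ·Lreg`, where `Lcls` is inverse-frequency-weighted binary
   cross-entropy over points and `Lreg = Σ|t − t̄|` an optional L1 term.
2. **Instance separation (CornDBSCAN)** — DBSCAN over the seedling points
   with `minpts = 3` and the neighbourhood radius estimated from the data:
   `eps = (1/N) Σᵢ dᵢ⁽ᵏ⁾`, the mean distance of each point to its k-th
   nearest neighbour (k = 55). Noise points get label −1; predicted
   clusters are matched to ground-truth plants with the Hungarian
   algorithm, maximizing summed IoU.
3. **Alignment and scaling** — RANSAC ground-plane detection, Rodrigues
   rotation of the plane normal onto +z
   (`θ = cos⁻¹(m·n / |m||n|)`), and the metric scale factor
   `k = L_real / L_virtual` from a reference object (the 25 cm tray side).
4. **Traits per plant** — height `H = z_max − z_min`; canopy width as the
   horizontal AABB diagonal `√(L² + W²)`; volume as occupied 0.1 cm voxels
   `V = Σ Vᵢ`; surface area by ball-pivoting reconstruction (0.2 cm ball)
   with triangle areas from Heron's formula `A = Σ Sⱼ`.

A synthetic tray-scene generator with ground truth known by construction
makes every stage testable end-to-end, and the six standard cloud
augmentations (fake dropout, clipped jitter, per-axis rotation, scaling,
shuffling, translation) plus the 8:1:1 split reproduce the usual training
data pipeline.

## Worked example

```r
library(corncloud)

## a synthetic 25 cm tray with 3 seedlings, tilted 12 degrees
sc <- generateScene(sceneSpec(nPlants = 3, tiltAngleDeg = 12, seed = 42))
sc$cloud
#> LabeledCloud with 3300 points
#>   seedling points: 1800
#>   plant instances: 3
#>   extent: x [-0.185, 24.9]  y [-0.187, 24.5]  z [0.132, 18.8]

## segment (here: ground-truth labels), cluster, align, scale, measure
traits <- phenotypeScene(sc$cloud, seed = 1)
traits$assignment
#> InstanceAssignment: 3 clusters, 0 noise points (eps = 1.003, k = 55, minpts = 3)
print(traits$records, digits = 3)
#>   plant_id height_cm canopy_cm volume_cm3 area_cm2 n_points
#> 1        1      14.5      6.23      0.532     9.71      600
#> 2        2      14.6      5.71      0.518     8.96      600
#> 3        3      10.1      4.43      0.458     6.20      600
```

The adaptive eps (1.0 cm here) sits well below the guaranteed 2.5 cm
inter-plant clearance, so each seedling becomes exactly one cluster.
Heights and canopy widths match the generator's manifest (14.5/14.6/10.1 cm
and 6.24/5.73/4.44 cm) to within a few tenths of a percent after the tilt
is removed by the RANSAC + Rodrigues alignment. Voxel volume and mesh area
are sampling-density-limited measurements of the point set, not of the
underlying solid, and are reported as such.

To train the segmentation network instead of using stored labels:

```r
scenes <- lapply(1:40, function(s)
  generateScene(sceneSpec(nPlants = 2 + s %% 5, tiltAngleDeg = 10,
                          seed = s))$cloud)
state <- trainNet(scenes[1:32], scenes[33:36], netConfig(seed = 1, batch = 8))
labels <- predictCloud(scenes[[40]], state)
semanticMetrics(labels, semanticLabels(scenes[[40]]))
```

A thin command-line front end (`inst/scripts/corncloud`) exposes the
pipeline stages (`synth`, `augment`, `train`, `segment`, `cluster`,
`evaluate`, `phenotype`, `run`) over `runPipeline()`, which writes
machine-readable receipts (seed + file hashes) per stage.

## Package layout

- `R/cloudio.R` — labeled text I/O, PLY export
- `R/synthgen.R` — synthetic tray scenes + ground-truth manifest
- `R/augment.R` — the six augmentations and the 8:1:1 dataset builder
- `R/cornnet.R`, `R/nn-tape.R` — the attention-augmented point network and
  its autodiff tape
- `R/instseg.R`, `R/hungarian.R` — CornDBSCAN and instance matching
- `R/metrics.R` — semantic and instance segmentation metrics
- `R/pheno.R` — alignment, scaling and the four traits
- `R/pipeline.R` — stage orchestration with receipts
- `vignettes/corncloud-methods.Rmd` — modelling assumptions, parameter
  choices, numerical details and limitations
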