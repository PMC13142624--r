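# tubetrace

Semi-automated 3D tracking and reconstruction of epithelial tubules —
renal nephrons, seminiferous tubules and kindred structures — in
cleared-tissue volumetric microscopy.

Dense voxel-wise segmentation of whole organs is intractable for
millimetre-long, densely packed, convoluted tubules. `tubetrace`
reformulates the problem as stepwise vector tracking: from a seed pair it
follows each tubule's centerline, at every step sampling and segmenting a
2D plane orthogonal to the forward direction and re-centering on the mask
centroid. Three recovery modules keep the tracker alive through the
morphology and staining changes that defeat plain tracking:

* **Adaptive parameter scaling** — the step size `S = round(d'/5)`, the
  segmentation diameter jitter `J = round(d'/3)` and the plane side
  `D = round(2.5 d')` all derive from a running-average cross-section
  diameter `d'` (initialized at 34 µm, clamped to [0.8, 50] µm).
* **Rotational search** — eccentric cross-sections (a bend or orientation
  error) trigger a sweep of candidate planes rotated about the fitted
  ellipse's minor axis over ±60° in 10° steps; the roundest candidate's
  normal becomes the new forward direction.
* **Troubleshooting with model switching** — segmentation failures trigger
  a two-stage multi-hypothesis workflow over a 10-slice local slab: the
  current model over the diameter sweep {d', d'−J, d'+J}, then the full
  model suite; a depth-consistent consensus selects the mask, and the
  best-agreeing hypothesis supplies the model and diameter used from then
  on.

Tracks that defeat every module are flagged into a file-based
human-in-the-loop queue; a one-or-few-click correction resumes automated
tracking. Downstream, the package turns tracks into voxel-level
reconstructions, straightened (curved-planar-reformation) stacks and
longitudinal cut-through views, morphometric profiles (diameter, curvature
κ = 1/R_circ, torsion from osculating-plane dihedrals), whole-tubule
nuclei cytometry in 20-µm windows, branch/reconnection topology of merged
track networks, and spermatogenic-wave staging of seminiferous
cross-sections (hierarchical dark / sparse-clusters / dense-clusters
classifier with thresholds a, b, c, d; defaults a = 2.5, b = 0.02, c = 86,
d = 0.62, smoothed with a 2-mm rolling mode).

A parametric phantom generator produces synthetic tubular volumes with
complete ground truth (centerlines, radii, voxel masks, planted nuclei,
staining-pattern runs, junctions) and is the basis of the entire test
suite.

## Worked example

Track a U-turn tubule phantom (radius 15 µm, wall-bright staining,
anisotropic 3×1×1 µm voxels), profile it, and compare the reconstruction
with ground truth:

```r
library(tubetrace)

spec <- tubePhantomSpec(
  centerline = list(model = "arc", start = c(30, 25, 18), direction = c(0, 0, 1),
                    axis = c(0, 1, 0), radiusUm = 90, angleDeg = 180,
                    straightBeforeUm = 110, straightAfterUm = 135),
  radius = list(profile = "constant", radiusUm = 15),
  intensity = list(contrast = 2, background = 100, wallThicknessUm = 8),
  noiseSd = 20, spacing = c(3, 1, 1), shape = c(85, 51, 240), seed = 21)
phantom <- makeTubePhantom(spec)
phantom$volume
#> VoxelGrid 'carbohydrate': 85 x 51 x 240 voxels (z,y,x), spacing 3 x 1 x 1 um
#>   extent: 255 x 51 x 240 um, intensity range [6.48, 285]

models <- list(segmentationModel("wall", "builtin-threshold"),
               segmentationModel("lumen", "builtin-lumen"))
track <- trackTubule(phantom$volume, seeds = rbind(c(30, 25, 22), c(30, 25, 29)),
                     config = trackingConfig(), models = models, id = "demo")
track
#> Track 'demo': 86 nodes, length 513.1 um, status 'terminated_boundary'
#>   mean diameter 30.0 um; RS used 0, TS used 0, manual 0

profile <- morphometricProfiles(track, stepUm = 5)
summary(profile[, c("diameter", "curvature")])
#>     diameter       curvature
#>  Min.   :29.58   Min.   :0.0002089
#>  Median :29.97   Median :0.0081891
#>  Max.   :30.38   Max.   :0.0150260

rec <- interpolateCrossSections(track, phantom$volume)
metrics <- maskMetrics(rec, maskArray(phantom$truth))
cat(sprintf("reconstruction vs truth: IoU %.3f, F1 %.3f\n", metrics$iou, metrics$f1))
#> reconstruction vs truth: IoU 0.889, F1 0.942
```

The tracker recovers the 30-µm calibre to within half a micrometre, the
curvature profile peaks at κ ≈ 0.011 µm⁻¹ = 1/90 through the turn, and the
voxel reconstruction overlaps the ground-truth mask at IoU 0.89.

A thin command-line wrapper over the same functions is installed at
`inst/cli/tubetrace.R` (subcommands `phantom`, `track`, `straighten`,
`profile`, `wavestage`).

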