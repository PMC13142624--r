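---
title: "Tracking and reconstructing tubular structures: models, parameters and design choices"
author: "tubetrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and reconstructing tubular structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tubetrace)
```

# The problem and the model

Epithelial tubules — renal nephrons, seminiferous tubules, collecting ducts —
are long, densely packed, convoluted structures whose function is organized
along their length. Dense voxel-wise 3D segmentation of whole organs is
computationally intractable and poorly conditioned where tubule boundaries
are ambiguous. `tubetrace` instead follows each tubule as a one-dimensional
object: starting from a user-supplied seed pair, the tracker repeatedly

1. estimates the forward direction from the two most recent centerline
   nodes,
2. proposes the next node one adaptive step `S` ahead,
3. samples a square plane of side `D` orthogonal to the forward direction
   (trilinear interpolation at native resolution),
4. segments the plane and selects the mask overlapping the plane centre, and
5. repositions the node to the mask centroid, updating the forward
   direction from the correction.

The ordered cross-sections are then interpolated into a voxel-level 3D
reconstruction, straightened views, morphometric profiles (length, diameter,
curvature, torsion), nuclei cytometry, and — for seminiferous tubules — a
staging of the spermatogenic wave.

# Adaptive runtime parameters

Three runtime parameters derive from the running-average cross-section
diameter `d'` (mean of up to `window = 10` recent node diameters, clamped to
`[dMin, dMax] = [0.8, 50]` micrometres, initialized at 34 micrometres):

* step size `S = round(d'/kStep)` with `kStep = 5`,
* segmentation diameter jitter `J = round(d'/kJitter)` with `kJitter = 3`,
* plane side `D = round(d' * kDim)` with `kDim = 2.5`.

At the initial diameter this gives `S = 7`, `J = 11`, `D = 85` micrometres.
The window length `W = 10` is a package default: long enough to suppress
per-frame segmentation jitter, short enough to follow the ~40 to ~16
micrometre calibre transitions of real nephrons within a few node steps.
All quantities are computed and applied in micrometres (not pixels), so the
tracker behaves identically across voxel spacings.

# Segmentation backends

The built-in backends replace learned cell-segmentation models so the whole
pipeline is testable without trained weights; a plugin registry
(`registerSegmentationBackend()`) preserves drop-in use of learned models.
Two properties of learned cell segmenters are modelled explicitly, because
the recovery modules exist to compensate for them:

* **Diameter-prior sensitivity.** Objects whose equivalent diameter falls
  outside `[0.45, 2.2]` times the configured diameter prior are not
  segmented. Cell models configured for a 40-micrometre calibre miss a
  16-micrometre thin limb; this is precisely what the troubleshooting
  diameter sweep (`d'`, `d'-J`, `d'+J`) recovers.
* **Shape prior.** Objects with second-moment eccentricity above 0.9 are
  not segmented: generalist cell models handle round-to-elliptical objects
  and fail on elongated tube-like profiles. Without this property, a plain
  intensity threshold segments arbitrarily elongated oblique cuts and the
  orientation-recovery machinery would be dead code.

`builtin-threshold` applies Otsu's threshold (computed over in-bounds pixels
only; out-of-bounds padding is defined background), fills holes — so a
bright-walled tubule with a dim lumen yields the full lumen-plus-wall disk —
and applies both priors. `builtin-lumen` runs the same pipeline on the
inverted image and discards components touching the raster border or the
out-of-bounds padding, capturing the lumen disk of wall-bright tubules; it
serves as the second model of the default suite, with a genuinely different
failure profile.

# Recovery modules

**Rotational search** fires when the selected mask is eccentric
(eccentricity at or above `eccentricityTrigger`). The plane rotates about the
in-plane minor axis of the fitted ellipse, `r = -sin(phi) u + cos(phi) v`,
over -60..60 degrees in 10-degree steps (13 candidates); each candidate is
re-segmented and the roundest wins, its normal becoming the new forward
direction. The trigger default is 0.71 — the eccentricity of a 45-degree
oblique cut through a circular tube. This was a genuinely open choice: we
measured that masks from smooth bends never exceed ~0.5 under adaptive
stepping (the per-step turn of a bend with radius of curvature three
diameters is `S/Rc = 1/15` radian regardless of scale), so a near-1 trigger
would never fire before outright segmentation failure. The trigger must also
sit below the backends' 0.9 elongation-rejection limit, or no mask would
ever be available to define the rotation axis. When rotational search is
disabled, an eccentric cross-section is treated as a failed segmentation
and escalates to troubleshooting — a shape-prior backend would not have
produced it.

**Troubleshooting and model switching** engages when no centre mask is
found. Stage 1 applies the current model over the diameter sweep to a local
slab (10 slices deep, target plane first, slices one pixel pitch apart along
the forward direction, sharing the target plane's in-plane axes). The
hypotheses are combined by per-pixel majority vote over the *non-empty*
hypotheses — hypotheses that found nothing anywhere abstain. A strict
majority over all hypotheses would make single-good-hypothesis recovery
(the very point of the diameter sweep: only one sweep arm can see a thin
limb) structurally impossible. Depth consistency is enforced by keeping the
26-connected component that contains the target-plane centre and spans at
least half the slab. Stage 2 repeats the procedure across the full model
suite. The hypothesis whose target-plane centre mask best agrees with the
consensus (IoU; ties toward the incumbent model, then the larger union)
supplies the adopted model and diameter; the running-average window is
re-seeded with the adopted diameter, since the old window reflects the
pre-transition calibre. If both stages fail, the track is flagged into a
file-based correction queue with a snapshot of the runtime parameters; a
one-or-few-click correction (`applyCorrection()`) appends manual nodes and
resumes automated tracking. One exception: when the volume face clips the
central region the cross-section would occupy (the sampled plane is more
than 20% out-of-bounds within 0.75 d' of its centre), a recovery failure is
a boundary termination, not a queue entry — the tubule is leaving the
volume, and no human correction could continue it.

**Stall detection** is ground-truth-free: a new node landing within
`0.25 S` of a node more than three steps back (backtracking/looping), or a
forward reversal (dot product below -0.5), flags the track.

# Track merging and branch points

Tracks are merged by Euclidean distance between centerlines (longest first,
resampled at half the merge tolerance): a fully covered track is absorbed,
an end-to-end continuation is spliced, and a lateral arrival is truncated at
a junction of degree 3. The first junction between a pair of tracks is a
branch point; any further junction between the same pair — a segment
rejoining the tubule it already joins — is a reconnection and is not counted
as an additional branch point. The default merge tolerance (15 micrometres,
roughly one tubule radius) is configurable; seminiferous-scale analyses use
larger values. Merge termination during tracking begins only after the
track has travelled three tolerances from its seed, so a track seeded beside
an existing centerline (at a junction) can escape before being declared a
duplicate.

# Reconstruction and straightening

Each node's mask is encoded as a radial contour function about its centroid
(64 spokes); centroids, rotation-minimizing frames and radial functions are
linearly interpolated between consecutive nodes at sub-voxel arc-length
steps and stamped as filled polygons at native resolution. The radial
encoding assumes approximately star-convex cross-sections, which holds for
tubule lumina; strongly non-convex masks would alias to their star-convex
hull. Straightened stacks resample orthogonal planes at uniform arc length
with rotation-minimizing frames (no spurious twist); the longitudinal
cut-through view takes the central row of each frame by default (a maximum
projection is available), giving the wall-bright tube its characteristic
two bright lines one diameter apart.

# Morphometry

Centerlines are resampled uniformly and lightly smoothed (3-point moving
average) to suppress segmentation jitter. Curvature is the inverse
circumradius of consecutive point triples; torsion is the signed dihedral
angle between consecutive osculating planes divided by the arc step. Both
converge to the analytic values of parametric test curves as the step
shrinks; the acceptance suite checks a line, a circle (kappa = 1/R) and a
helix (kappa = R/(R^2+c^2), |tau| = c/(R^2+c^2)) at 5% tolerance with
monotone convergence over three step sizes. Loop-type classification uses
two rules reported together: thin-limb length below 1.4 mm means short-loop,
and entry into the inner-medulla region means long-loop (the region rule
wins when they disagree, being definitional). Tracking quality against a
ground-truth centerline counts *breaks*: excessive deviation (default
threshold twice the local truth diameter), a stall, or a segmentation
failure no module recovers; after each break the harness restarts from the
point of deviation.

# Cytometry

Nuclei are detected in the DNA channel crop of a reconstruction's bounding
box. The built-in detector thresholds midway between the median (robust
background) and the 99.9th intensity percentile — a global Otsu is unstable
when foreground occupies a fraction of a percent of the crop — labels
26-connected components, and splits components above 1.6 expected nucleus
volumes by deterministic k-means (farthest-point initialization). A nucleus
belongs to a tubule exactly when its centroid voxel is foreground in the
voxel reconstruction (equivalent to a mesh-interior test at native
resolution, without meshing). Densities are profiled in consecutive 20
micrometre windows along the centerline: linear density is count per window;
volumetric density divides by the reconstruction volume inside the window
(undefined, reported as missing, where that volume is zero); segment-level
values are means across the segment's windows.

# Spermatogenic-wave staging

Cross-sections are classified hierarchically: a frame is **dark** when the
area above `threshold1 = a x median(in-mask intensity)` is below fraction
`b` of the cross-section; remaining frames are re-thresholded at raw
intensity `c`, and the frame is **sparse_clusters** when the two largest
8-connected components hold less than fraction `d` of the bright area, else
**dense_clusters**. The `a x median` reading of the first threshold is a
package convention: a dimensionless multiplier near 2.5 cannot be a raw
intensity, and the in-mask median is the natural exposure-invariant anchor;
the denominator of `d` is likewise read as the total bright area. Both
conventions are configurable. Labels are smoothed with a rolling modal
window (2 mm default; ties resolve to the previous smoothed label). Runs of
equal labels are collapsed, transition direction follows the cyclic order
dark - sparse - dense - dark, a complete wave is three consecutive runs
covering all classes in one direction, and a reversal is a change of
direction between adjacent transitions. Calibration is an exhaustive grid
search maximizing macro-F1 (ties toward smaller `a`, then `c`, `b`, `d`);
per-frame statistics are precomputed so the sweep costs almost nothing
beyond one connected-component analysis per frame per candidate `c`.

# The phantom generator

Phantoms provide complete ground truth (centerline with arc length and
radius, voxel mask, planted nuclei, class runs, junctions) for every test in
the package. Walls are rendered from the exact distance to the resampled
centerline (point-to-segment distance on a ~1.5 micrometre chord, with a
separable closed form for straight tubes); tubes end flat, not with
hemispherical caps, so mask volumes match the analytic cylinder; noise is
additive Gaussian clipped at zero. Tubes may run out through a volume face
they are heading into — real tubules cross slab boundaries, and boundary
termination needs a tube that reaches the face — but reject with a
diagnostic when they would graze a face sideways.

Study conditions are fixed once per suite:

* **Straight-tube suite**: 1 mm tube, radius 20 um, 1 um isotropic voxels,
  contrast 3 over background 100, noise sd 20 — bright, cortex-quality
  carbohydrate staining.
* **Recovery suite**: contrast 2 and noise sd 15-20 (deep-tissue quality).
  The diameter-step phantom switches abruptly from 40 to 16 um — abrupt on
  purpose: a taper longer than `W x S` is absorbed by the running average
  and never exercises the sweep. The sharp-bend phantom is a crumpled
  serpentine with ~90-degree vertices spaced 90 um (three tube diameters,
  the characteristic bend radius at path scale) at (2, 1, 1) um spacing:
  convoluted tubules are crumpled, not smoothly toroidal, and we measured
  that a smooth three-diameter arc is followed essentially perfectly by
  adaptive-step centroid-corrected tracking, leaving nothing for
  orientation recovery to do.
* **Wave phantom**: a 22.2 mm seminiferous-scale tube (radius 110 um) at
  5 um isotropic voxels, with eleven 2-mm class runs (three forward periods,
  then a reversed half-period). Class structure is deterministic per run:
  dark runs carry only rare trace flecks; sparse runs carry 3-8 thin bright
  cords evenly spaced around the epithelium (counts cycling per run);
  dense runs carry two thick bright cords at the epithelial rim plus two
  thin satellites. Decoy structures make each classifier threshold
  identifiable rather than degenerate: four faint cords at intensity 135
  (between 2x and 2.5x the epithelial median of 60) break the stage-1
  multiplier below 2.5; a sub-surface ring at intensity 75 welds everything
  into one giant component whenever the second threshold dips below it,
  ruining the cluster statistics for c = 70; the satellites hold the dense
  cluster-dominance fraction near 0.77 (killing d = 0.9), and the
  three-cord sparse runs push it to ~0.34 (killing d = 0.3). Under these
  conditions the grid search recovers a = 2.5, b = 0.02, c = 86, d = 0.62
  as the unique optimum of its grid.

What passing these tests does and does not show: the phantoms exercise the
algorithmic contracts — recovery logic, consensus semantics, geometric
estimators, counting rules — under controlled, idealized staining. They do
not model optical point-spread anisotropy beyond voxel spacing, tile
stitching artifacts, incomplete clearing, or the learned-model failure
modes of real data; performance numbers on phantoms are not predictions of
performance on tissue.

# Problem sizes and numerical choices

The shipped test and acceptance workloads use desk-scale volumes (1-22 mm
tubes, 1-6 million voxels) chosen so each suite completes in seconds to a
couple of minutes on one CPU. Trilinear interpolation is used everywhere
(exact for locally linear intensity, deterministic); plane pixel pitch
defaults to the volume's finest lateral spacing; rotational-search ties
break toward the smallest rotation angle, troubleshooting ties toward the
incumbent model; all randomness is funnelled through explicit seeds, and
per-track seeds derive deterministically from the global seed and track id,
so a four-worker run equals the serial run track for track.

# Known limitations

* Junction regions deflect centroid-corrected tracking: where two tubules
  merge, the union cross-section drags the node a few micrometres off-axis
  (shallow-angle branches more than steep ones). The merging machinery is
  therefore the authority on branch topology, not the per-track path
  through a junction.
* The radial contour encoding cannot represent strongly non-convex
  cross-sections.
* The built-in backends are threshold-based stand-ins: they reproduce the
  diameter- and shape-sensitivity of learned models, not their texture
  priors.
* On-disk volumes use a TIFF-per-level multiscale directory; chunked
  cloud-native formats are out of scope for this implementation.
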