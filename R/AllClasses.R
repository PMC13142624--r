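#' @import methods
#' @importFrom stats approx median rpois runif rnorm quantile sd setNames
#' @importFrom utils head tail write.csv read.csv modifyList
NULL

#' VoxelGrid: a 3D intensity raster with physical spacing
#'
#' A single-channel, single-resolution 3D image. Axis order is (z, y, x)
#' throughout the package: `intensities(x)[i, j, k]` sits at world position
#' `origin + (c(i, j, k) - 1) * spacing` in micrometres.
#'
#' @slot intensities 3D numeric array, dim (nz, ny, nx).
#' @slot spacing numeric(3), voxel spacing in um per axis (z, y, x).
#' @slot origin numeric(3), world position of voxel (1,1,1) in um.
#' @slot channel character scalar channel identifier.
#' @export
setClass("VoxelGrid", representation(
  intensities = "array", spacing = "numeric", origin = "numeric",
  channel = "character"))

setValidity("VoxelGrid", function(object) {
  if (length(dim(object@intensities)) != 3) return("intensities must be a 3D array")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    return("spacing must be 3 strictly positive values (z, y, x)")
  if (length(object@origin) != 3) return("origin must have 3 values")
  if (any(dim(object@intensities) < 1)) return("shape must be strictly positive")
  TRUE
})

#' MultiscaleVolume: an ordered resolution pyramid of VoxelGrids
#'
#' Level 1 is the native resolution; each subsequent level is downsampled by
#' `factor` per axis, with spacing scaled accordingly.
#'
#' @slot levels list of [VoxelGrid-class] objects, finest first.
#' @slot factor integer downsampling factor between consecutive levels.
#' @export
setClass("MultiscaleVolume", representation(levels = "list", factor = "numeric"))

setValidity("MultiscaleVolume", function(object) {
  if (length(object@levels) < 1) return("needs at least one level")
  if (!all(vapply(object@levels, is, TRUE, "VoxelGrid")))
    return("all levels must be VoxelGrid objects")
  if (object@factor < 1) return("factor must be >= 1")
  for (k in seq_along(object@levels)[-1]) {
    expec <- object@levels[[1]]@spacing * object@factor^(k - 1)
    if (any(abs(object@levels[[k]]@spacing - expec) > 1e-6 * expec))
      return(sprintf("level %d spacing is not level-1 spacing x factor^%d", k, k - 1))
  }
  TRUE
})

#' OrientedPlane: a square sampling plane in world coordinates
#'
#' @slot center numeric(3) world um.
#' @slot normal,u,v numeric(3) orthonormal right-handed frame ({n, u, v}).
#' @slot side numeric scalar, plane side length D in um.
#' @slot pitch numeric scalar, pixel pitch in um.
#' @export
setClass("OrientedPlane", representation(
  center = "numeric", normal = "numeric", u = "numeric", v = "numeric",
  side = "numeric", pitch = "numeric"))

setValidity("OrientedPlane", function(object) {
  g <- rbind(object@normal, object@u, object@v)
  if (any(dim(g) != c(3, 3))) return("normal, u, v must each have 3 components")
  if (max(abs(g %*% t(g) - diag(3))) > 1e-6) return("{normal, u, v} must be orthonormal")
  if (sum(cross3(object@u, object@v) * object@normal) < 0)
    return("{normal, u, v} must be right-handed (u x v = normal)")
  if (object@side <= 0) return("side must be > 0")
  if (object@pitch <= 0) return("pitch must be > 0")
  TRUE
})

#' PlaneImage: the resampled raster of an OrientedPlane
#'
#' Pixel (row, col) sits at
#' `center + (col - c0) * pitch * u + (row - r0) * pitch * v` with (r0, c0)
#' the raster centre. Out-of-bounds pixels are 0 and flagged in `oob`.
#'
#' @slot pixels numeric matrix (square, side = round(side/pitch)).
#' @slot oob logical matrix, TRUE where the sample fell outside the volume.
#' @slot plane the source [OrientedPlane-class].
#' @export
setClass("PlaneImage", representation(
  pixels = "matrix", oob = "matrix", plane = "OrientedPlane"))

#' SegmentationOutcome: labelled objects found in a PlaneImage
#'
#' @slot labels integer matrix; 0 = background, objects numbered 1..k.
#' @slot modelId character, the segmentation model that produced it.
#' @slot success logical, TRUE if at least one object was found.
#' @export
setClass("SegmentationOutcome", representation(
  labels = "matrix", modelId = "character", success = "logical"))

#' CrossSectionMask: the selected binary tubule cross-section
#'
#' @slot mask logical matrix (same raster as the source PlaneImage).
#' @slot plane the source [OrientedPlane-class].
#' @slot centroidPx numeric(2) (row, col) centroid in pixels.
#' @slot centroidWorld numeric(3) centroid in world um.
#' @slot areaUm2 numeric, mask area in um^2.
#' @slot equivDiameterUm numeric, 2*sqrt(A/pi) in um.
#' @slot ellipse list(major, minor, phi, eccentricity): second-moment ellipse
#'   fit with semi-axes in um, in-plane orientation phi (radians, measured from
#'   the u axis), and eccentricity sqrt(1 - (minor/major)^2).
#' @slot modelId character, model that produced the mask.
#' @export
setClass("CrossSectionMask", representation(
  mask = "matrix", plane = "OrientedPlane", centroidPx = "numeric",
  centroidWorld = "numeric", areaUm2 = "numeric", equivDiameterUm = "numeric",
  ellipse = "list", modelId = "character"))

#' TrackingConfig: parameters of the stepwise vector tracker
#'
#' Defaults follow the published operating point: scaling factors
#' k_step = 5, k_jitter = 3, k_dim = 2.5 applied to the running-average
#' diameter d'; d' initialized at 34 um and clamped to [0.8, 50] um; rotational
#' search sweeps -60..60 degrees in 10 degree steps; the troubleshooting slab
#' is 10 slices deep.
#'
#' @slot kStep,kJitter,kDim dimensionless scaling factors.
#' @slot window running-average window W (node count).
#' @slot dMin,dMax,dInit um diameter clamp bounds and initial value.
#' @slot rotationRange,rotationStep degrees for the rotational search sweep.
#' @slot eccentricityTrigger eccentricity at or above which rotational search
#'   fires.
#' @slot tsDepth troubleshooting slab depth in slices.
#' @slot maxSteps cap on tracking iterations.
#' @slot stallRadiusFactor fraction of S within which revisiting an old node
#'   (> stallLookback steps back) counts as a stall.
#' @slot stallLookback steps back beyond which proximity counts as a stall.
#' @slot reversalDot forward-direction dot product below which a step counts
#'   as backtracking.
#' @slot mergeToleranceUm centerline distance below which tracks merge.
#' @slot enableAP,enableRS,enableTS module switches (adaptive parameters,
#'   rotational search, troubleshooting) for ablation studies.
#' @slot rngSeed integer seed for any configured stochastic component.
#' @export
setClass("TrackingConfig", representation(
  kStep = "numeric", kJitter = "numeric", kDim = "numeric", window = "numeric",
  dMin = "numeric", dMax = "numeric", dInit = "numeric",
  rotationRange = "numeric", rotationStep = "numeric",
  eccentricityTrigger = "numeric", tsDepth = "numeric", maxSteps = "numeric",
  stallRadiusFactor = "numeric", stallLookback = "numeric", reversalDot = "numeric",
  mergeToleranceUm = "numeric",
  enableAP = "logical", enableRS = "logical", enableTS = "logical",
  rngSeed = "numeric"))

setValidity("TrackingConfig", function(object) {
  if (!(object@dMin > 0 && object@dMin <= object@dInit && object@dInit <= object@dMax))
    return("need 0 < dMin <= dInit <= dMax")
  if (abs((object@rotationRange / object@rotationStep) %% 1) > 1e-9)
    return("rotationStep must divide rotationRange evenly")
  if (object@tsDepth < 1) return("tsDepth must be >= 1")
  TRUE
})

#' Track: an ordered centerline with per-node cross-section information
#'
#' @slot nodes data.frame with columns z, y, x (world um), s (arc length um),
#'   diameter (um), model (character), rotationalSearch, troubleshoot,
#'   manualCorrection (logical flags).
#' @slot masks list of [CrossSectionMask-class] (or NULL) per node.
#' @slot seeds 2 x 3 matrix of the seed pair (world um).
#' @slot status one of active, flagged, complete, terminated_boundary,
#'   terminated_merge.
#' @slot flags data.frame of open flag-queue entries (see [flagQueue()]).
#' @slot interventionLog list of recovery/correction events.
#' @slot id character track identifier.
#' @export
setClass("Track", representation(
  nodes = "data.frame", masks = "list", seeds = "matrix", status = "character",
  flags = "data.frame", interventionLog = "list", id = "character"))

setValidity("Track", function(object) {
  if (nrow(object@nodes) > 1 && any(diff(object@nodes$s) <= 0))
    return("arc length must be strictly increasing along a track")
  if (!object@status %in% c("active", "flagged", "complete",
                            "terminated_boundary", "terminated_merge"))
    return("unknown track status")
  TRUE
})

#' TubuleNetwork: merged tracks plus junction graph
#'
#' @slot tracks list of [Track-class].
#' @slot junctions data.frame with columns z, y, x, degree, kind
#'   ("branch" or "reconnection"), trackA, trackB.
#' @export
setClass("TubuleNetwork", representation(tracks = "list", junctions = "data.frame"))

#' TubuleVolumeMask: voxel-level reconstruction of one tubule
#'
#' Stored as a bounding-box crop plus the (1-based) index offset of the crop
#' within the source volume.
#'
#' @slot mask logical 3D array (crop).
#' @slot offset integer(3) index of crop voxel (1,1,1) within the source grid.
#' @slot spacing,origin geometry of the source [VoxelGrid-class].
#' @slot trackId character source track.
#' @export
setClass("TubuleVolumeMask", representation(
  mask = "array", offset = "integer", spacing = "numeric", origin = "numeric",
  trackId = "character"))

#' StraightenedStack: arc-length-resampled orthogonal cross-sections
#'
#' @slot frames numeric 3D array (side, side, nFrames).
#' @slot intervalUm frame spacing along the centerline in um.
#' @slot arcLengths numeric, arc length of each frame in um.
#' @slot planes list of the [OrientedPlane-class] per frame.
#' @export
setClass("StraightenedStack", representation(
  frames = "array", intervalUm = "numeric", arcLengths = "numeric",
  planes = "list"))

#' WaveClassifierParams: thresholds of the spermatogenic-wave classifier
#'
#' The hierarchical classifier: a frame is "dark" when the area above
#' threshold1 = a x median(in-mask intensity) occupies less than fraction b of
#' the cross-section; remaining frames are re-thresholded at raw intensity c
#' and called "sparse_clusters" when the two largest 8-connected components
#' hold less than fraction d of the bright area, else "dense_clusters".
#' Defaults are the published grid-search optimum a = 2.5, b = 0.02, c = 86,
#' d = 0.62 with a 2-mm smoothing window.
#'
#' @slot a multiplier on the in-mask median intensity (threshold 1).
#' @slot b area fraction in [0, 1] separating the dark class.
#' @slot c raw intensity threshold 2.
#' @slot d cluster-dominance fraction in [0, 1].
#' @slot smoothingWindowUm rolling-window width for label smoothing, um.
#' @export
setClass("WaveClassifierParams", representation(
  a = "numeric", b = "numeric", c = "numeric", d = "numeric",
  smoothingWindowUm = "numeric"))

setValidity("WaveClassifierParams", function(object) {
  if (object@a <= 0 || object@c <= 0) return("a and c must be > 0")
  if (object@b < 0 || object@b > 1 || object@d < 0 || object@d > 1)
    return("b and d must lie in [0, 1]")
  TRUE
})

#' StageSequence: per-frame wave classes along a tubule
#'
#' @slot frames data.frame with columns s (arc length um), raw (class),
#'   smoothed (class, NA until [smoothLabels()] is applied).
#' @slot waves data.frame of complete waves (startUm, endUm, direction).
#' @slot reversals integer count of direction changes.
#' @export
setClass("StageSequence", representation(
  frames = "data.frame", waves = "data.frame", reversals = "integer"))

#' FrameSelectionParams: SSIM-based training-frame selection thresholds
#'
#' A frame along a centerline is kept only when (1 - SSIM vs the previously
#' kept frame) >= alpha, (1 - mean SSIM vs all kept frames) >= beta, and it is
#' at least minInterval frames from the last kept one.
#'
#' @slot alpha local-change threshold in [0, 1].
#' @slot beta global-change threshold in [0, 1].
#' @slot minInterval minimum index interval between kept frames (>= 0).
#' @export
setClass("FrameSelectionParams", representation(
  alpha = "numeric", beta = "numeric", minInterval = "numeric"))

setValidity("FrameSelectionParams", function(object) {
  if (object@alpha < 0 || object@alpha > 1 || object@beta < 0 || object@beta > 1)
    return("alpha and beta must lie in [0, 1]")
  if (object@minInterval < 0) return("minInterval must be >= 0")
  TRUE
})

#' PhantomTruth: complete ground truth of a synthetic phantom
#'
#' @slot centerline data.frame z, y, x, s, radius (um).
#' @slot mask logical 3D array, the true tubule voxels (lumen + wall).
#' @slot nuclei data.frame z, y, x, inLumen, tubule (1-based tube index).
#' @slot classes data.frame sStart, sEnd, class (wave phantoms only).
#' @slot junctions data.frame z, y, x, s, kind ("branch"/"reconnection").
#' @slot tubeMasks list of per-tube logical arrays (multi-tube phantoms).
#' @export
setClass("PhantomTruth", representation(
  centerline = "data.frame", mask = "array", nuclei = "data.frame",
  classes = "data.frame", junctions = "data.frame", tubeMasks = "list"))
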