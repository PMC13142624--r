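#' Create a VoxelGrid
#'
#' @param intensities 3D numeric array, axis order (z, y, x).
#' @param spacing voxel spacing in um per axis (z, y, x).
#' @param origin world position (um) of voxel (1,1,1); default c(0,0,0).
#' @param channel channel identifier.
#' @return A [VoxelGrid-class].
#' @examples
#' vg <- voxelGrid(array(0, c(4, 5, 6)), spacing = c(2, 1, 1))
#' dim(vg)
#' @export
voxelGrid <- function(intensities, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                      channel = "raw") {
  new("VoxelGrid", intensities = intensities, spacing = as.numeric(spacing),
      origin = as.numeric(origin), channel = channel)
}

#' World coordinates of a voxel index, and back
#'
#' Continuous (possibly fractional) 1-based voxel indices map to world
#' micrometres via `origin + (index - 1) * spacing`.
#'
#' @param volume a [VoxelGrid-class].
#' @param index numeric(3) or n x 3 matrix of 1-based (z, y, x) indices.
#' @param world numeric(3) or n x 3 matrix of world um.
#' @return A matrix (or vector) of the converted coordinates.
#' @export
indexToWorld <- function(volume, index) {
  index <- if (is.matrix(index)) index else matrix(index, ncol = 3)
  sweep(sweep(index - 1, 2, spacing(volume), "*"), 2, origin(volume), "+")
}

#' @rdname indexToWorld
#' @export
worldToIndex <- function(volume, world) {
  world <- if (is.matrix(world)) world else matrix(world, ncol = 3)
  sweep(sweep(world, 2, origin(volume), "-"), 2, spacing(volume), "/") + 1
}

#' Create an OrientedPlane
#'
#' If `u` is omitted an arbitrary in-plane frame orthogonal to `normal` is
#' constructed; `v` is always recomputed as `normal x u` so the frame is
#' right-handed.
#'
#' @param center plane centre, world um (z, y, x).
#' @param normal plane normal (need not be unit length).
#' @param side side length D in um.
#' @param pitch pixel pitch in um.
#' @param u optional in-plane axis.
#' @return An [OrientedPlane-class].
#' @export
orientedPlane <- function(center, normal, side, pitch, u = NULL) {
  normal <- normalize(normal)
  if (is.null(u)) u <- orthoComplement(normal)
  u <- normalize(u - sum(u * normal) * normal)
  v <- cross3(normal, u)
  new("OrientedPlane", center = as.numeric(center), normal = normal,
      u = u, v = v, side = side, pitch = pitch)
}

#' Create a TrackingConfig
#'
#' All defaults are the published operating point; see
#' [TrackingConfig-class] for the meaning of each parameter.
#'
#' @param kStep,kJitter,kDim scaling factors for S, J, D.
#' @param window running-average window W in nodes.
#' @param dMin,dMax,dInit diameter clamp bounds and initial value, um.
#' @param rotationRange,rotationStep rotational search sweep, degrees.
#' @param eccentricityTrigger eccentricity that triggers rotational search.
#' @param tsDepth troubleshooting slab depth, slices.
#' @param maxSteps iteration cap.
#' @param stallRadiusFactor,stallLookback,reversalDot stall detection knobs.
#' @param mergeToleranceUm centerline merge tolerance, um.
#' @param enableAP,enableRS,enableTS recovery module switches.
#' @param rngSeed seed for configured stochastic components.
#' @return A [TrackingConfig-class].
#' @examples
#' trackingConfig()
#' @export
trackingConfig <- function(kStep = 5, kJitter = 3, kDim = 2.5, window = 10,
                           dMin = 0.8, dMax = 50, dInit = 34,
                           rotationRange = 60, rotationStep = 10,
                           eccentricityTrigger = 0.71, tsDepth = 10,
                           maxSteps = 2000, stallRadiusFactor = 0.25,
                           stallLookback = 3, reversalDot = -0.5,
                           mergeToleranceUm = 15,
                           enableAP = TRUE, enableRS = TRUE, enableTS = TRUE,
                           rngSeed = 1L) {
  new("TrackingConfig", kStep = kStep, kJitter = kJitter, kDim = kDim,
      window = window, dMin = dMin, dMax = dMax, dInit = dInit,
      rotationRange = rotationRange, rotationStep = rotationStep,
      eccentricityTrigger = eccentricityTrigger, tsDepth = tsDepth,
      maxSteps = maxSteps, stallRadiusFactor = stallRadiusFactor,
      stallLookback = stallLookback, reversalDot = reversalDot,
      mergeToleranceUm = mergeToleranceUm, enableAP = enableAP,
      enableRS = enableRS, enableTS = enableTS, rngSeed = rngSeed)
}

#' Create WaveClassifierParams
#'
#' Defaults are the published grid-search optimum.
#'
#' @param a,b,c,d classifier thresholds; see [WaveClassifierParams-class].
#' @param smoothingWindowUm label smoothing window, um.
#' @return A [WaveClassifierParams-class].
#' @export
waveClassifierParams <- function(a = 2.5, b = 0.02, c = 86, d = 0.62,
                                 smoothingWindowUm = 2000) {
  new("WaveClassifierParams", a = a, b = b, c = c, d = d,
      smoothingWindowUm = smoothingWindowUm)
}

#' Create FrameSelectionParams
#'
#' @param alpha,beta SSIM change thresholds in [0, 1].
#' @param minInterval minimum frame interval between kept frames.
#' @return A [FrameSelectionParams-class].
#' @export
frameSelectionParams <- function(alpha = 0.08, beta = 0.08, minInterval = 20) {
  new("FrameSelectionParams", alpha = alpha, beta = beta,
      minInterval = minInterval)
}

# Internal: empty node table / flag table with the canonical columns.
emptyNodes <- function() {
  data.frame(z = numeric(0), y = numeric(0), x = numeric(0), s = numeric(0),
             diameter = numeric(0), model = character(0),
             rotationalSearch = logical(0), troubleshoot = logical(0),
             manualCorrection = logical(0), stringsAsFactors = FALSE)
}

emptyFlags <- function() {
  data.frame(trackId = character(0), nodeIndex = integer(0),
             reason = character(0), S = numeric(0), J = numeric(0),
             D = numeric(0), dPrime = numeric(0), stringsAsFactors = FALSE)
}

emptyJunctions <- function() {
  data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
             degree = integer(0), kind = character(0),
             trackA = character(0), trackB = character(0),
             stringsAsFactors = FALSE)
}
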