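#' @name tubetrace-accessors
#' @title Accessors for tubetrace classes
#' @description Small accessor generics for the package's S4 containers.
#' @param x an object.
#' @return The corresponding slot value.
NULL

#' @rdname tubetrace-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname tubetrace-accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname tubetrace-accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))
#' @rdname tubetrace-accessors
#' @export
setGeneric("channelId", function(x) standardGeneric("channelId"))
#' @rdname tubetrace-accessors
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))
#' @rdname tubetrace-accessors
#' @export
setGeneric("getLevel", function(x, level) standardGeneric("getLevel"))
#' @rdname tubetrace-accessors
#' @export
setGeneric("trackNodes", function(x) standardGeneric("trackNodes"))
#' @rdname tubetrace-accessors
#' @export
setGeneric("trackStatus", function(x) standardGeneric("trackStatus"))
#' @rdname tubetrace-accessors
#' @export
setGeneric("trackLength", function(x) standardGeneric("trackLength"))
#' @rdname tubetrace-accessors
#' @export
setGeneric("flagQueue", function(x) standardGeneric("flagQueue"))
#' @rdname tubetrace-accessors
#' @export
setGeneric("junctions", function(x) standardGeneric("junctions"))
#' @rdname tubetrace-accessors
#' @export
setGeneric("networkTracks", function(x) standardGeneric("networkTracks"))
#' @rdname tubetrace-accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname tubetrace-accessors
#' @export
setGeneric("equivDiameter", function(x) standardGeneric("equivDiameter"))
#' @rdname tubetrace-accessors
#' @export
setGeneric("eccentricity", function(x) standardGeneric("eccentricity"))
#' @rdname tubetrace-accessors
#' @export
setGeneric("centroidWorld", function(x) standardGeneric("centroidWorld"))

setMethod("intensities", "VoxelGrid", function(x) x@intensities)
setMethod("spacing", "VoxelGrid", function(x) x@spacing)
setMethod("origin", "VoxelGrid", function(x) x@origin)
setMethod("channelId", "VoxelGrid", function(x) x@channel)
setMethod("spacing", "MultiscaleVolume", function(x) x@levels[[1]]@spacing)
setMethod("nLevels", "MultiscaleVolume", function(x) length(x@levels))
setMethod("getLevel", "MultiscaleVolume", function(x, level) {
  if (level < 1 || level > length(x@levels))
    stop("level ", level, " does not exist (pyramid has ", length(x@levels), " levels)")
  x@levels[[level]]
})
setMethod("trackNodes", "Track", function(x) x@nodes)
setMethod("trackStatus", "Track", function(x) x@status)
setMethod("trackLength", "Track", function(x)
  if (nrow(x@nodes) == 0) 0 else max(x@nodes$s) - min(x@nodes$s))
setMethod("flagQueue", "Track", function(x) x@flags)
setMethod("junctions", "TubuleNetwork", function(x) x@junctions)
setMethod("networkTracks", "TubuleNetwork", function(x) x@tracks)
setMethod("maskArray", "TubuleVolumeMask", function(x) x@mask)
setMethod("maskArray", "PhantomTruth", function(x) x@mask)
setMethod("equivDiameter", "CrossSectionMask", function(x) x@equivDiameterUm)
setMethod("eccentricity", "CrossSectionMask", function(x) x@ellipse$eccentricity)
setMethod("centroidWorld", "CrossSectionMask", function(x) x@centroidWorld)

setMethod("dim", "VoxelGrid", function(x) dim(x@intensities))

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("VoxelGrid '%s': %d x %d x %d voxels (z,y,x), spacing %s um\n",
              object@channel, d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = " x ")))
  cat(sprintf("  extent: %s um, intensity range [%.3g, %.3g]\n",
              paste(signif(d * object@spacing, 4), collapse = " x "),
              min(object@intensities), max(object@intensities)))
})

setMethod("show", "MultiscaleVolume", function(object) {
  cat(sprintf("MultiscaleVolume: %d levels, factor %g\n",
              length(object@levels), object@factor))
  for (k in seq_along(object@levels)) {
    d <- dim(object@levels[[k]]@intensities)
    cat(sprintf("  level %d: %d x %d x %d @ %s um\n", k, d[1], d[2], d[3],
                paste(signif(object@levels[[k]]@spacing, 3), collapse = "/")))
  }
})

setMethod("show", "Track", function(object) {
  cat(sprintf("Track '%s': %d nodes, length %.1f um, status '%s'\n",
              object@id, nrow(object@nodes), trackLength(object), object@status))
  if (nrow(object@nodes) > 0)
    cat(sprintf("  mean diameter %.1f um; RS used %d, TS used %d, manual %d\n",
                mean(object@nodes$diameter, na.rm = TRUE),
                sum(object@nodes$rotationalSearch), sum(object@nodes$troubleshoot),
                sum(object@nodes$manualCorrection)))
  if (nrow(object@flags) > 0)
    cat(sprintf("  open flags: %s\n", paste(object@flags$reason, collapse = ", ")))
})

setMethod("show", "TubuleNetwork", function(object) {
  jk <- table(factor(object@junctions$kind, levels = c("branch", "reconnection")))
  cat(sprintf("TubuleNetwork: %d tracks, %d branch junction(s), %d reconnection(s)\n",
              length(object@tracks), jk[["branch"]], jk[["reconnection"]]))
})

setMethod("show", "CrossSectionMask", function(object) {
  cat(sprintf("CrossSectionMask: area %.1f um^2, d = %.1f um, e = %.3f (model '%s')\n",
              object@areaUm2, object@equivDiameterUm,
              object@ellipse$eccentricity, object@modelId))
})

setMethod("show", "StraightenedStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("StraightenedStack: %d frames of %d x %d px at %.1f um intervals\n",
              d[3], d[1], d[2], object@intervalUm))
})

setMethod("show", "StageSequence", function(object) {
  cat(sprintf("StageSequence: %d frames", nrow(object@frames)))
  if (!all(is.na(object@frames$smoothed)))
    cat(sprintf(", %d complete wave(s), %d reversal(s)",
                nrow(object@waves), object@reversals))
  cat("\n")
})

setMethod("show", "TrackingConfig", function(object) {
  cat(sprintf(paste0(
    "TrackingConfig: k_step=%g k_jitter=%g k_dim=%g W=%g, d' init %g um in ",
    "[%g, %g] um\n  rotation +/-%g deg step %g, e-trigger %g, TS depth %g; ",
    "modules AP=%s RS=%s TS=%s\n"),
    object@kStep, object@kJitter, object@kDim, object@window, object@dInit,
    object@dMin, object@dMax, object@rotationRange, object@rotationStep,
    object@eccentricityTrigger, object@tsDepth,
    object@enableAP, object@enableRS, object@enableTS))
})
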