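# Whole-tubule nuclei cytometry: detect nuclei in the DNA channel within a
# reconstruction's bounding box, assign them by centroid membership in the
# voxel reconstruction, and profile densities in consecutive windows along
# the centerline.

#' Detect nuclei in a (cropped) DNA-channel volume
#'
#' Builtin backend: global Otsu threshold over the crop, 26-connected
#' component labelling, and splitting of oversized components (more than
#' 1.6x the expected single-nucleus volume) by deterministic k-means on the
#' voxel coordinates. A plugin backend registered via
#' [registerSegmentationBackend()] may be used instead; its contract is
#' `fun(intensityArray, radiusVox, options) -> integer label array`.
#'
#' @param volume the nuclei-channel [VoxelGrid-class].
#' @param bbox optional list(lo, hi) of 1-based index bounds (e.g. a
#'   reconstruction's bounding box); default is the whole volume.
#' @param radiusUm expected nucleus radius (um).
#' @param backend "builtin" or a registered plugin key.
#' @return data.frame(z, y, x, volumeUm3, track) of nucleus centroids in
#'   world um (`track` is NA until [assignNuclei()]).
#' @export
detectNuclei <- function(volume, bbox = NULL, radiusUm = 4,
                         backend = "builtin") {
  dm <- dim(volume@intensities)
  if (is.null(bbox)) bbox <- list(lo = c(1L, 1L, 1L), hi = dm)
  lo <- pmax(as.integer(bbox$lo), 1L); hi <- pmin(as.integer(bbox$hi), dm)
  crop <- volume@intensities[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                             drop = FALSE]
  empty <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                      volumeUm3 = numeric(0), track = character(0))
  if (length(crop) == 0) return(empty)
  voxVol <- prod(volume@spacing)
  vExp <- 4 / 3 * pi * radiusUm^3
  if (backend == "builtin") {
    # blob detection on a dark background: the histogram is overwhelmingly
    # background, so a global Otsu is unstable; threshold midway between the
    # robust background level (median) and the bright level (99.9th
    # percentile) instead
    med <- stats::median(crop)
    hi <- stats::quantile(crop, 0.999, names = FALSE)
    if (hi - med < 1e-9) return(empty)
    bin <- crop > med + 0.4 * (hi - med)
    if (mean(bin) > 0.2) return(empty)   # no sparse bright blobs present
    lab <- labelComponents(bin, full = TRUE)
  } else {
    if (!exists(backend, envir = backendRegistry))
      stop("nucleus segmentation backend '", backend, "' is not registered")
    fun <- get(backend, envir = backendRegistry)
    lab <- fun(crop, radiusUm / min(volume@spacing), list())
  }
  if (max(lab) == 0) return(empty)
  out <- NULL
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k, arr.ind = TRUE)
    vol <- nrow(idx) * voxVol
    if (vol < 0.1 * vExp) next            # speckle
    nSplit <- max(1L, round(vol / vExp))
    if (vol < 1.6 * vExp) nSplit <- 1L
    grp <- splitPointsKmeans(idx, nSplit)
    for (g in seq_len(max(grp))) {
      sub <- idx[grp == g, , drop = FALSE]
      ctr <- colMeans(sub) + lo - 1
      out <- rbind(out, data.frame(
        z = volume@origin[1] + (ctr[1] - 1) * volume@spacing[1],
        y = volume@origin[2] + (ctr[2] - 1) * volume@spacing[2],
        x = volume@origin[3] + (ctr[3] - 1) * volume@spacing[3],
        volumeUm3 = nrow(sub) * voxVol, track = NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) empty else out
}

#' Assign nuclei to a reconstruction by centroid membership
#'
#' A nucleus belongs to the tubule exactly when its centroid voxel is
#' foreground in the tubule's voxel reconstruction.
#'
#' @param nuclei data.frame from [detectNuclei()] (or with z, y, x columns).
#' @param reconstruction a [TubuleVolumeMask-class].
#' @return The nuclei data.frame with `track` filled in for members.
#' @export
assignNuclei <- function(nuclei, reconstruction) {
  if (nrow(nuclei) == 0) return(nuclei)
  m <- reconstruction
  idx <- round(sweep(sweep(as.matrix(nuclei[, c("z", "y", "x")]), 2,
                           m@origin), 2, m@spacing, "/")) + 1
  idx <- sweep(idx, 2, as.numeric(m@offset) - 1)   # into crop coordinates
  d <- dim(m@mask)
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
        idx[, 2] >= 1 & idx[, 2] <= d[2] &
        idx[, 3] >= 1 & idx[, 3] <= d[3]
  inside <- rep(FALSE, nrow(nuclei))
  inside[ok] <- m@mask[idx[ok, , drop = FALSE]]
  if (!"track" %in% names(nuclei)) nuclei$track <- NA_character_
  nuclei$track[inside] <- m@trackId
  nuclei
}

#' Nuclei density profiles along a tubule
#'
#' Each assigned nucleus is mapped to the arc length of its nearest
#' centerline point; counts are taken in consecutive windows (20 um by
#' default). Linear density is count/window; volumetric density is count
#' divided by the reconstruction volume inside the window (reported as NA
#' where that volume is zero).
#'
#' @param nuclei assigned nuclei data.frame (only rows whose `track`
#'   matches the reconstruction's are counted).
#' @param track the [Track-class] providing the centerline.
#' @param reconstruction the [TubuleVolumeMask-class].
#' @param windowUm window width (um).
#' @return data.frame(sStart, sEnd, count, linearDensity, volumeUm3,
#'   volumetricDensity).
#' @export
densityProfiles <- function(nuclei, track, reconstruction, windowUm = 20) {
  if (windowUm <= 0) stop("window must be > 0")
  pts <- as.matrix(track@nodes[, c("z", "y", "x")])
  rs <- resamplePolyline(pts, min(windowUm / 4, 5))
  L <- max(rs$s)
  starts <- seq(0, L, by = windowUm)
  starts <- starts[starts < L]
  sel <- nuclei[!is.na(nuclei$track) &
                  nuclei$track == reconstruction@trackId, , drop = FALSE]
  sNuc <- if (nrow(sel) > 0)
    distanceToPolyline(as.matrix(sel[, c("z", "y", "x")]),
                       rs$points, s = rs$s)$s else numeric(0)
  # per-window reconstruction volume: assign each foreground voxel to the
  # window of its nearest centerline arc length
  fg <- which(reconstruction@mask, arr.ind = TRUE)
  volPerWindow <- rep(0, length(starts))
  if (nrow(fg) > 0) {
    w <- sweep(sweep(fg + matrix(as.numeric(reconstruction@offset) - 1,
                                 nrow(fg), 3, byrow = TRUE) - 1,
                     2, reconstruction@spacing, "*"),
               2, reconstruction@origin, "+")
    # subsample foreground voxels for the volume estimate on large crops
    nFg <- nrow(w)
    if (nFg > 200000) {
      keep <- seq(1, nFg, length.out = 200000)
      w <- w[keep, , drop = FALSE]
      scaleUp <- nFg / length(keep)
    } else scaleUp <- 1
    sVox <- distanceToPolyline(w, rs$points, s = rs$s)$s
    win <- pmin(findInterval(sVox, starts), length(starts))
    tab <- tabulate(win, nbins = length(starts))
    volPerWindow <- tab * prod(reconstruction@spacing) * scaleUp
  }
  winNuc <- if (length(sNuc) > 0)
    pmin(findInterval(sNuc, starts), length(starts)) else integer(0)
  counts <- tabulate(winNuc, nbins = length(starts))
  data.frame(
    sStart = starts, sEnd = pmin(starts + windowUm, L), count = counts,
    linearDensity = counts / windowUm,
    volumeUm3 = volPerWindow,
    volumetricDensity = ifelse(volPerWindow > 0, counts / volPerWindow, NA))
}
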