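# Volume access: trilinear sampling of oriented planes and slabs, pyramid
# construction, and a TIFF-per-level multiscale directory format.

# Vectorized trilinear interpolation at world points (n x 3 um).
# Out-of-bounds points (beyond the voxel-centre hull) return 0 with oob TRUE.
trilinearSample <- function(volume, world) {
  a <- volume@intensities
  dm <- dim(a)
  idx <- worldToIndex(volume, world)
  oob <- idx[, 1] < 1 | idx[, 1] > dm[1] |
         idx[, 2] < 1 | idx[, 2] > dm[2] |
         idx[, 3] < 1 | idx[, 3] > dm[3]
  i0 <- pmin(pmax(floor(idx[, 1]), 1), dm[1] - 1L)
  j0 <- pmin(pmax(floor(idx[, 2]), 1), dm[2] - 1L)
  k0 <- pmin(pmax(floor(idx[, 3]), 1), dm[3] - 1L)
  if (dm[1] == 1) i0 <- rep(1, nrow(idx))
  if (dm[2] == 1) j0 <- rep(1, nrow(idx))
  if (dm[3] == 1) k0 <- rep(1, nrow(idx))
  fi <- pmin(pmax(idx[, 1] - i0, 0), 1)
  fj <- pmin(pmax(idx[, 2] - j0, 0), 1)
  fk <- pmin(pmax(idx[, 3] - k0, 0), 1)
  nz <- dm[1]; nzy <- dm[1] * dm[2]
  i1 <- pmin(i0 + 1, dm[1]); j1 <- pmin(j0 + 1, dm[2]); k1 <- pmin(k0 + 1, dm[3])
  lin <- function(i, j, k) a[i + (j - 1) * nz + (k - 1) * nzy]
  val <-
    lin(i0, j0, k0) * (1 - fi) * (1 - fj) * (1 - fk) +
    lin(i1, j0, k0) * fi       * (1 - fj) * (1 - fk) +
    lin(i0, j1, k0) * (1 - fi) * fj       * (1 - fk) +
    lin(i0, j0, k1) * (1 - fi) * (1 - fj) * fk +
    lin(i1, j1, k0) * fi       * fj       * (1 - fk) +
    lin(i1, j0, k1) * fi       * (1 - fj) * fk +
    lin(i0, j1, k1) * (1 - fi) * fj       * fk +
    lin(i1, j1, k1) * fi       * fj       * fk
  val[oob] <- 0
  list(values = val, oob = oob)
}

#' Sample an oriented plane from a volume
#'
#' Resamples the volume on a square raster of side `round(side/pitch)` pixels
#' centred on the plane centre, by trilinear interpolation at each pixel's
#' world position. Pixels outside the volume are 0 and flagged.
#'
#' @param volume a [VoxelGrid-class].
#' @param plane an [OrientedPlane-class].
#' @return A [PlaneImage-class].
#' @export
samplePlane <- function(volume, plane) {
  n <- max(2L, as.integer(round(plane@side / plane@pitch)))
  c0 <- (n + 1) / 2
  off <- (seq_len(n) - c0) * plane@pitch
  # row index varies along v, column index along u
  du <- rep(off, each = n)    # column offsets, one block per column
  dv <- rep(off, times = n)   # row offsets
  world <- cbind(
    plane@center[1] + du * plane@u[1] + dv * plane@v[1],
    plane@center[2] + du * plane@u[2] + dv * plane@v[2],
    plane@center[3] + du * plane@u[3] + dv * plane@v[3])
  smp <- trilinearSample(volume, world)
  new("PlaneImage",
      pixels = matrix(smp$values, nrow = n, ncol = n),
      oob = matrix(smp$oob, nrow = n, ncol = n),
      plane = plane)
}

# World position of plane pixel (row, col) (possibly fractional).
planePixelToWorld <- function(plane, row, col, n = NULL) {
  if (is.null(n)) n <- max(2L, as.integer(round(plane@side / plane@pitch)))
  c0 <- (n + 1) / 2
  du <- (col - c0) * plane@pitch
  dv <- (row - c0) * plane@pitch
  cbind(plane@center[1] + du * plane@u[1] + dv * plane@v[1],
        plane@center[2] + du * plane@u[2] + dv * plane@v[2],
        plane@center[3] + du * plane@u[3] + dv * plane@v[3])
}

#' Extract a slab of parallel plane images
#'
#' Slice j is the target plane translated `(j - 1) * pitch` along its normal;
#' slice 1 is the target plane itself. All slices share the target plane's
#' in-plane axes.
#'
#' @param volume a [VoxelGrid-class].
#' @param plane the target [OrientedPlane-class] (first slice).
#' @param depth number of slices (>= 1).
#' @return A list of [PlaneImage-class], length `depth`.
#' @export
extractLocalSlab <- function(volume, plane, depth) {
  depth <- as.integer(depth)
  if (depth < 1) stop("depth must be >= 1")
  lapply(seq_len(depth) - 1L, function(j) {
    pj <- plane
    pj@center <- plane@center + j * plane@pitch * plane@normal
    samplePlane(volume, pj)
  })
}

# 2x mean-downsample one level (handles odd trailing voxels by truncation).
downsample2 <- function(grid) {
  a <- grid@intensities
  dm <- dim(a)
  nd <- pmax(dm %/% 2, 1L)
  out <- array(0, dim = nd)
  cnt <- 0
  for (oz in 0:1) for (oy in 0:1) for (ox in 0:1) {
    iz <- pmin(seq(1 + oz, by = 2, length.out = nd[1]), dm[1])
    iy <- pmin(seq(1 + oy, by = 2, length.out = nd[2]), dm[2])
    ix <- pmin(seq(1 + ox, by = 2, length.out = nd[3]), dm[3])
    out <- out + a[iz, iy, ix, drop = FALSE]
    cnt <- cnt + 1
  }
  voxelGrid(out / cnt, spacing = grid@spacing * 2,
            origin = grid@origin + grid@spacing / 2, channel = grid@channel)
}

#' Build a multiscale pyramid from a single-resolution grid
#'
#' @param grid a [VoxelGrid-class] at native resolution.
#' @param nLevels number of pyramid levels (including the native one).
#' @return A [MultiscaleVolume-class] with 2x downsampling per level.
#' @export
buildPyramid <- function(grid, nLevels = 3) {
  levels <- vector("list", nLevels)
  levels[[1]] <- grid
  for (k in seq_len(nLevels - 1)) levels[[k + 1]] <- downsample2(levels[[k]])
  # downsample2 shifts the origin by half a voxel; the pyramid contract only
  # constrains spacing, but keep origins consistent for world-space sampling.
  new("MultiscaleVolume", levels = levels, factor = 2)
}

#' Write / load a multiscale volume directory
#'
#' The on-disk layout is one 32-bit float multi-page TIFF per pyramid level
#' (`level_1.tif`, `level_2.tif`, ...; pages are z-slices) plus a `meta.json`
#' holding spacing, origin, channel and the downsampling factor.
#'
#' @param volume a [MultiscaleVolume-class] or [VoxelGrid-class] (written as a
#'   single-level pyramid).
#' @param path directory to create/read.
#' @return `writeVolume` returns `path` invisibly; `loadVolume` returns a
#'   [VoxelGrid-class] for the requested level.
#' @export
writeVolume <- function(volume, path) {
  if (is(volume, "VoxelGrid")) volume <- new("MultiscaleVolume",
                                             levels = list(volume), factor = 2)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(volume@levels)) {
    g <- volume@levels[[k]]
    a <- g@intensities
    scale <- max(abs(a), 1e-12)
    pages <- lapply(seq_len(dim(a)[1]), function(i) a[i, , ] / scale)
    tiff::writeTIFF(pages, file.path(path, sprintf("level_%d.tif", k)),
                    bits.per.sample = 32)
    if (k == 1) meta <- list(
      format = "tubetrace-multiscale", factor = volume@factor,
      channel = g@channel, levels = length(volume@levels),
      spacing = g@spacing, origin = g@origin, shape = dim(a),
      intensity_scale = scale)
    else meta$intensity_scale <- c(meta$intensity_scale, scale)
  }
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeVolume
#' @param level pyramid level to load (1 = native).
#' @param channel expected channel name; an error is raised on mismatch.
#' @export
loadVolume <- function(path, level = 1, channel = NULL) {
  metaPath <- file.path(path, "meta.json")
  if (!file.exists(metaPath))
    stop("'", path, "' is not a tubetrace multiscale volume (no meta.json)")
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  if (!identical(meta$format, "tubetrace-multiscale"))
    stop("unknown volume format: ", meta$format)
  if (level < 1 || level > meta$levels)
    stop("level ", level, " does not exist (", meta$levels, " available)")
  if (!is.null(channel) && !identical(channel, meta$channel))
    stop("channel '", channel, "' not present (volume holds '", meta$channel, "')")
  pages <- tiff::readTIFF(file.path(path, sprintf("level_%d.tif", level)),
                          all = TRUE)
  a <- array(0, dim = c(length(pages), dim(pages[[1]])))
  for (i in seq_along(pages)) a[i, , ] <- pages[[i]]
  a <- a * meta$intensity_scale[level]
  fac <- meta$factor^(level - 1)
  voxelGrid(a, spacing = meta$spacing * fac,
            origin = meta$origin + (fac - 1) * meta$spacing / 2,
            channel = meta$channel)
}

#' Read a subregion of a VoxelGrid
#'
#' @param volume a [VoxelGrid-class].
#' @param zlim,ylim,xlim integer(2) inclusive 1-based index ranges.
#' @return A [VoxelGrid-class] crop with adjusted origin.
#' @export
cropVolume <- function(volume, zlim, ylim, xlim) {
  dm <- dim(volume@intensities)
  zlim <- pmin(pmax(as.integer(zlim), 1L), dm[1])
  ylim <- pmin(pmax(as.integer(ylim), 1L), dm[2])
  xlim <- pmin(pmax(as.integer(xlim), 1L), dm[3])
  a <- volume@intensities[zlim[1]:zlim[2], ylim[1]:ylim[2], xlim[1]:xlim[2],
                          drop = FALSE]
  voxelGrid(a, spacing = volume@spacing,
            origin = volume@origin +
              (c(zlim[1], ylim[1], xlim[1]) - 1) * volume@spacing,
            channel = volume@channel)
}
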