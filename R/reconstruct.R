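# Voxel-level reconstruction from tracked cross-sections, curved-planar
# straightening, longitudinal cut-through views, and region annotation.

# Radial contour function of a mask about its centroid: max foreground
# radius along nTheta rays (um). Assumes approximately star-convex masks
# (true of tubule cross-sections); see the methods vignette.
radialFunction <- function(mask, centroidPx, pitch, nTheta = 64) {
  n <- nrow(mask)
  th <- (seq_len(nTheta) - 1) * 2 * pi / nTheta
  rmaxPx <- max(n - centroidPx[1], centroidPx[1],
                n - centroidPx[2], centroidPx[2])
  steps <- seq(0, rmaxPx, by = 0.5)
  out <- numeric(nTheta)
  for (k in seq_len(nTheta)) {
    rr <- centroidPx[1] + steps * sin(th[k])
    cc <- centroidPx[2] + steps * cos(th[k])
    ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
    fg <- rep(FALSE, length(steps))
    fg[ok] <- mask[cbind(round(rr[ok]), round(cc[ok]))]
    hit <- which(fg)
    out[k] <- if (length(hit) == 0) 0 else steps[max(hit)] * pitch
  }
  out
}

#' Interpolate tracked cross-sections into a voxel reconstruction
#'
#' Each node's mask contour is encoded as a radial function about its
#' centroid (64 spokes in the node's plane frame); centroids, frames and
#' radial functions are linearly interpolated between consecutive nodes at
#' sub-voxel arc-length steps and each interpolated polygon is stamped as
#' filled foreground at native resolution.
#'
#' @param track a [Track-class] with at least 2 mask-bearing nodes.
#' @param volume the source [VoxelGrid-class] (defines the voxel raster).
#' @return A [TubuleVolumeMask-class].
#' @export
interpolateCrossSections <- function(track, volume) {
  withMask <- which(!vapply(track@masks, is.null, TRUE))
  if (length(withMask) < 2)
    stop("reconstruction needs at least 2 nodes with cross-section masks")
  sp <- volume@spacing; orig <- volume@origin
  dm <- dim(volume@intensities)
  minSp <- min(sp)
  nTheta <- 64
  th <- (seq_len(nTheta) - 1) * 2 * pi / nTheta
  ct <- cos(th); st <- sin(th)
  nodes <- lapply(withMask, function(i) {
    m <- track@masks[[i]]
    list(center = m@centroidWorld,
         u = m@plane@u, v = m@plane@v, normal = m@plane@normal,
         r = radialFunction(m@mask, m@centroidPx, m@plane@pitch, nTheta),
         s = track@nodes$s[i])
  })
  # global crop bounds
  allC <- do.call(rbind, lapply(nodes, `[[`, "center"))
  rmax <- max(vapply(nodes, function(n) max(n$r), 0))
  lo <- pmax(floor((apply(allC, 2, min) - rmax - 2 - orig) / sp) + 1, 1)
  hi <- pmin(ceiling((apply(allC, 2, max) + rmax + 2 - orig) / sp) + 1, dm)
  crop <- array(FALSE, dim = hi - lo + 1)
  ndc <- dim(crop)
  # in-plane sample offsets at half-voxel pitch, stamped per interpolated disk
  pitchS <- minSp / 2
  stampDisk <- function(center, u, v, r) {
    rM <- max(r)
    if (rM <= 0) return()
    g <- seq(-rM, rM, by = pitchS)
    ga <- expand.grid(a = g, b = g)
    rho <- sqrt(ga$a^2 + ga$b^2)
    ang <- atan2(ga$b, ga$a) %% (2 * pi)
    rAt <- approx(c(th, 2 * pi), c(r, r[1]), xout = ang)$y
    keep <- rho <= rAt
    if (!any(keep)) return()
    pts <- cbind(center[1] + ga$a[keep] * u[1] + ga$b[keep] * v[1],
                 center[2] + ga$a[keep] * u[2] + ga$b[keep] * v[2],
                 center[3] + ga$a[keep] * u[3] + ga$b[keep] * v[3])
    idx <- round(sweep(sweep(pts, 2, orig), 2, sp, "/")) + 1
    ok <- idx[, 1] >= lo[1] & idx[, 1] <= hi[1] &
          idx[, 2] >= lo[2] & idx[, 2] <= hi[2] &
          idx[, 3] >= lo[3] & idx[, 3] <= hi[3]
    if (!any(ok)) return()
    lin <- (idx[ok, 1] - lo[1] + 1) +
      (idx[ok, 2] - lo[2]) * ndc[1] +
      (idx[ok, 3] - lo[3]) * ndc[1] * ndc[2]
    crop[lin] <<- TRUE
  }
  for (i in seq_len(length(nodes) - 1)) {
    a <- nodes[[i]]; b <- nodes[[i + 1]]
    seg <- vecNorm(b$center - a$center)
    nStep <- max(2, ceiling(seg / (minSp / 2)) + 1)
    tt <- seq(0, 1, length.out = nStep)
    for (t0 in tt) {
      ctr <- (1 - t0) * a$center + t0 * b$center
      nrm <- normalize((1 - t0) * a$normal + t0 * b$normal)
      uu <- (1 - t0) * a$u + t0 * b$u
      uu <- normalize(uu - sum(uu * nrm) * nrm)
      vv <- cross3(nrm, uu)
      rr <- (1 - t0) * a$r + t0 * b$r
      stampDisk(ctr, uu, vv, rr)
    }
  }
  new("TubuleVolumeMask", mask = crop, offset = as.integer(lo), spacing = sp,
      origin = orig, trackId = track@id)
}

#' Straighten a tubule into a stack of orthogonal cross-sections
#'
#' The track centerline is resampled at a uniform arc-length interval and an
#' orthogonal plane is sampled at each position using rotation-minimizing
#' frames (no spurious twist between consecutive frames).
#'
#' @param volume a [VoxelGrid-class].
#' @param track a [Track-class] (or an n x 3 matrix of centerline points).
#' @param intervalUm frame spacing along the centerline (um); must be > 0
#'   and at most the track length.
#' @param sideUm plane side length; default 2.5x the track's maximum node
#'   diameter (or 100 um if no diameters are known).
#' @return A [StraightenedStack-class] with `floor(L/interval) + 1` frames.
#' @export
straightenTubule <- function(volume, track, intervalUm, sideUm = NULL) {
  pts <- if (is(track, "Track")) as.matrix(track@nodes[, c("z", "y", "x")])
         else as.matrix(track)
  L <- polylineLength(pts)
  if (intervalUm <= 0) stop("interval must be > 0")
  if (intervalUm > L)
    stop(sprintf("interval (%.1f um) exceeds the track length (%.1f um)",
                 intervalUm, L))
  if (is.null(sideUm)) {
    dmax <- if (is(track, "Track")) max(track@nodes$diameter, na.rm = TRUE)
            else NA
    sideUm <- if (is.finite(dmax)) 2.5 * dmax else 100
  }
  nFrames <- floor(L / intervalUm) + 1
  sOut <- (seq_len(nFrames) - 1) * intervalUm
  rs <- resamplePolyline(pts, min(intervalUm, 2))
  fr <- rmfFrames(rs$points)
  pitch <- planePitch(volume)
  side <- max(2L, as.integer(round(sideUm / pitch)))
  frames <- array(0, dim = c(side, side, nFrames))
  planes <- vector("list", nFrames)
  for (k in seq_len(nFrames)) {
    i <- which.min(abs(rs$s - sOut[k]))
    iN <- min(i + 1, nrow(rs$points))
    iP <- max(i - 1, 1)
    nrm <- normalize(rs$points[iN, ] - rs$points[iP, ])
    uu <- normalize(fr$e1[i, ] - sum(fr$e1[i, ] * nrm) * nrm)
    pl <- new("OrientedPlane", center = rs$points[i, ], normal = nrm,
              u = uu, v = cross3(nrm, uu), side = side * pitch, pitch = pitch)
    img <- samplePlane(volume, pl)
    frames[, , k] <- img@pixels
    planes[[k]] <- pl
  }
  new("StraightenedStack", frames = frames, intervalUm = intervalUm,
      arcLengths = sOut, planes = planes)
}

#' Longitudinal cut-through view of a straightened stack
#'
#' @param stack a [StraightenedStack-class].
#' @param mode "central" (default) takes the central row of each frame;
#'   "max" takes the row-wise maximum projection.
#' @return Numeric matrix (frame side x frame count): column j is the cut of
#'   frame j.
#' @export
longitudinalView <- function(stack, mode = c("central", "max")) {
  mode <- match.arg(mode)
  d <- dim(stack@frames)
  if (d[3] == 0) stop("empty stack")
  out <- matrix(0, d[1], d[3])
  c0 <- round((d[1] + 1) / 2)
  for (j in seq_len(d[3])) {
    fr <- stack@frames[, , j]
    out[, j] <- if (mode == "central") fr[c0, ] else apply(fr, 1, max)
  }
  out
}

#' Write a straightened stack as a multi-page TIFF
#'
#' @param stack a [StraightenedStack-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeStraightenedStack <- function(stack, path) {
  sc <- max(stack@frames, 1e-12)
  pages <- lapply(seq_len(dim(stack@frames)[3]),
                  function(k) stack@frames[, , k] / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  invisible(path)
}

#' Assign region-atlas labels along a track
#'
#' @param track a [Track-class].
#' @param atlas a [VoxelGrid-class] of integer region labels aligned to the
#'   tracked volume (0 = unassigned).
#' @param labelMap optional named map from label values to region names
#'   (e.g. `c("1" = "cortex", "2" = "OSOM", "3" = "ISOM", "4" = "IM")`).
#' @return list(labels = per-node labels, transitions = data.frame(sUm,
#'   from, to) at arc lengths where consecutive labels differ).
#' @export
assignRegions <- function(track, atlas, labelMap = NULL) {
  nd <- track@nodes
  idx <- round(worldToIndex(atlas, as.matrix(nd[, c("z", "y", "x")])))
  dm <- dim(atlas@intensities)
  idx[, 1] <- pmin(pmax(idx[, 1], 1), dm[1])
  idx[, 2] <- pmin(pmax(idx[, 2], 1), dm[2])
  idx[, 3] <- pmin(pmax(idx[, 3], 1), dm[3])
  vals <- atlas@intensities[idx]
  labels <- as.character(vals)
  labels[vals == 0] <- "unassigned"
  if (!is.null(labelMap)) {
    mapped <- labelMap[labels]
    labels[!is.na(mapped)] <- mapped[!is.na(mapped)]
  }
  ch <- which(labels[-1] != labels[-length(labels)])
  transitions <- data.frame(
    sUm = (nd$s[ch] + nd$s[ch + 1]) / 2,
    from = labels[ch], to = labels[ch + 1], stringsAsFactors = FALSE)
  list(labels = labels, transitions = transitions)
}

#' Intersection-over-union and related metrics between two voxel masks
#'
#' @param predicted,truth logical arrays of identical geometry, or
#'   [TubuleVolumeMask-class] objects sharing a world frame (the union of
#'   their crops is compared).
#' @return list(iou, f1, precision, recall) over foreground voxels.
#' @export
maskMetrics <- function(predicted, truth) {
  if (is(predicted, "TubuleVolumeMask") || is(truth, "TubuleVolumeMask")) {
    expand <- function(m, lo, hi) {
      out <- array(FALSE, dim = hi - lo + 1)
      if (is(m, "TubuleVolumeMask")) {
        o <- m@offset; d <- dim(m@mask)
        out[(o[1]:(o[1] + d[1] - 1)) - lo[1] + 1,
            (o[2]:(o[2] + d[2] - 1)) - lo[2] + 1,
            (o[3]:(o[3] + d[3] - 1)) - lo[3] + 1] <- m@mask
      } else {
        d <- dim(m)
        out[(1:d[1]) - lo[1] + 1, (1:d[2]) - lo[2] + 1,
            (1:d[3]) - lo[3] + 1] <- m
      }
      out
    }
    bounds <- function(m) if (is(m, "TubuleVolumeMask"))
      list(lo = m@offset, hi = m@offset + dim(m@mask) - 1L)
    else list(lo = c(1L, 1L, 1L), hi = dim(m))
    bp <- bounds(predicted); bt <- bounds(truth)
    lo <- pmin(bp$lo, bt$lo); hi <- pmax(bp$hi, bt$hi)
    predicted <- expand(predicted, lo, hi)
    truth <- expand(truth, lo, hi)
  }
  tp <- sum(predicted & truth)
  fp <- sum(predicted & !truth)
  fn <- sum(!predicted & truth)
  if (tp + fp + fn == 0) stop("both masks are empty")
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  list(iou = tp / (tp + fp + fn), f1 = f1, precision = prec, recall = rec)
}
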