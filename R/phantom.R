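# Parametric tubular phantoms with complete ground truth. These emulate the
# imaging regimes the tracker must survive: bright tubule walls around dim
# lumina, diameter transitions (e.g. ~40 um proximal segments narrowing to
# ~16 um thin segments), sharp bends, branches with optional reconnection,
# planted nuclei, staining gaps, and periodic staining patterns along
# seminiferous-scale tubules.

#' PhantomSpec: parameters of a synthetic tubule phantom
#'
#' Construct with [tubePhantomSpec()].
#'
#' @slot centerline list describing the centerline model (see
#'   [tubePhantomSpec()]).
#' @slot radius list describing the radius profile along arc length.
#' @slot intensity list: model ("wall" or "solid"), background level,
#'   contrast (foreground mean / background mean), lumen level,
#'   wallThicknessUm.
#' @slot noiseSd additive Gaussian noise sd (intensity units; clipped at 0).
#' @slot spacing,shape,origin volume geometry ((z,y,x); um / voxels / um).
#' @slot branches list of branch specs (attachS, spec, reconnectS).
#' @slot nuclei list(densityPerUm, radiusUm, inLumenFraction) or empty.
#' @slot wave list describing a periodic staining pattern, or empty.
#' @slot gaps list of c(sStart, sEnd) arc-length intervals with no staining.
#' @slot seed integer RNG seed; output is reproducible given the seed.
#' @export
setClass("PhantomSpec", representation(
  centerline = "list", radius = "list", intensity = "list", noiseSd = "numeric",
  spacing = "numeric", shape = "numeric", origin = "numeric",
  branches = "list", nuclei = "list", wave = "list", gaps = "list",
  seed = "numeric"))

setValidity("PhantomSpec", function(object) {
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    return("spacing must be 3 positive values")
  if (length(object@shape) != 3 || any(object@shape < 2))
    return("shape must be 3 values >= 2")
  rmin <- minRadiusOfProfile(object@radius)
  if (rmin < 2 * max(object@spacing[2:3]))
    return(sprintf("radius (min %.2f um) must be >= 2x the max lateral voxel spacing", rmin))
  TRUE
})

#' Create a phantom specification
#'
#' Centerline models (`centerline$model`):
#' \describe{
#'   \item{line}{`start`, `direction`, `lengthUm`.}
#'   \item{arc}{`start`, `direction`, `axis` (rotation axis), `radiusUm`,
#'     `angleDeg`; optional `straightBeforeUm` / `straightAfterUm` lead-in and
#'     lead-out segments tangent to the arc.}
#'   \item{helix}{`center` (axis point at theta = 0), `radiusUm`, `riseUm`
#'     (rise per radian, the helix parameter c), `turns`. The helix axis is
#'     the world z axis, so centerline points satisfy
#'     (x - x0)^2 + (y - y0)^2 = R^2.}
#'   \item{sine}{`start`, `direction`, `transverse`, `amplitudeUm`,
#'     `wavelengthUm`, `lengthUm` (extent along `direction`).}
#'   \item{polyline}{`points`, an n x 3 matrix of world (z,y,x) um.}
#'   \item{randomwalk}{`start`, `direction`, `lengthUm`, `maxCurvature`
#'     (1/um); a smooth random walk whose discrete curvature never exceeds
#'     the bound.}
#' }
#'
#' Radius profiles (`radius$profile`): `constant` (`radiusUm`), `taper`
#' (`fromUm`, `toUm`, linear in arc length), `steps` (`breaks`, a data.frame
#' with columns `sUm`, `radiusUm`; piecewise-constant, value of the last
#' break at or before s).
#'
#' @param centerline,radius,intensity,nuclei,wave model descriptions (lists).
#' @param noiseSd Gaussian noise sd, intensity units.
#' @param spacing,shape,origin volume geometry, (z, y, x) order.
#' @param branches list of `list(attachS=, spec=, reconnectS=NULL)` entries;
#'   each child `spec` is a PhantomSpec whose centerline is translated so its
#'   first point lies on the parent centerline at arc length `attachS` (and,
#'   if `reconnectS` is given, warped so its last point rejoins the parent).
#' @param gaps list of `c(sStart, sEnd)` intervals where wall staining is
#'   absent (emulating local signal dropout).
#' @param seed integer seed; phantom generation is bit-reproducible.
#' @return A [PhantomSpec-class].
#' @examples
#' spec <- tubePhantomSpec(
#'   centerline = list(model = "line", start = c(27, 27, 20),
#'                     direction = c(0, 0, 1), lengthUm = 200),
#'   radius = list(profile = "constant", radiusUm = 20),
#'   shape = c(54, 54, 240))
#' @export
tubePhantomSpec <- function(centerline,
                            radius = list(profile = "constant", radiusUm = 20),
                            intensity = list(),
                            noiseSd = 20,
                            spacing = c(1, 1, 1),
                            shape,
                            origin = c(0, 0, 0),
                            branches = list(),
                            nuclei = list(),
                            wave = list(),
                            gaps = list(),
                            seed = 1L) {
  idef <- list(model = "wall", background = 100, contrast = 3,
               lumen = NULL, wallThicknessUm = 4)
  intensity <- modifyList(idef, intensity)
  if (is.null(intensity$lumen)) intensity$lumen <- intensity$background
  new("PhantomSpec", centerline = centerline, radius = radius,
      intensity = intensity, noiseSd = noiseSd, spacing = as.numeric(spacing),
      shape = as.numeric(shape), origin = as.numeric(origin),
      branches = branches, nuclei = nuclei, wave = wave, gaps = gaps,
      seed = seed)
}

minRadiusOfProfile <- function(radius) {
  switch(radius$profile,
         constant = radius$radiusUm,
         taper = min(radius$fromUm, radius$toUm),
         steps = min(radius$breaks$radiusUm),
         stop("unknown radius profile: ", radius$profile))
}

radiusAt <- function(radius, s) {
  switch(radius$profile,
         constant = rep(radius$radiusUm, length(s)),
         taper = {
           L <- radius$lengthUm
           radius$fromUm + (radius$toUm - radius$fromUm) * pmin(pmax(s / L, 0), 1)
         },
         steps = {
           br <- radius$breaks[order(radius$breaks$sUm), ]
           idx <- findInterval(s, br$sUm, rightmost.closed = FALSE)
           br$radiusUm[pmax(idx, 1)]
         })
}

# Build a centerline polyline at roughly hUm point spacing.
buildCenterline <- function(cl, hUm = 1) {
  pts <- switch(cl$model,
    line = {
      d <- normalize(cl$direction)
      s <- seq(0, cl$lengthUm, by = hUm)
      if (max(s) < cl$lengthUm) s <- c(s, cl$lengthUm)
      cbind(cl$start[1] + s * d[1], cl$start[2] + s * d[2], cl$start[3] + s * d[3])
    },
    arc = {
      d <- normalize(cl$direction)
      ax <- normalize(cl$axis)
      d <- normalize(d - sum(d * ax) * ax)
      R <- cl$radiusUm
      ang <- cl$angleDeg * pi / 180
      pre <- if (is.null(cl$straightBeforeUm)) 0 else cl$straightBeforeUm
      post <- if (is.null(cl$straightAfterUm)) 0 else cl$straightAfterUm
      out <- NULL
      p <- cl$start
      if (pre > 0) {
        s <- seq(0, pre, by = hUm)
        out <- rbind(out, t(sapply(s, function(si) p + si * d)))
        p <- p + pre * d
      }
      ctr <- p + R * cross3(ax, d)              # centre of curvature
      th <- seq(0, ang, by = hUm / R)
      if (max(th) < ang) th <- c(th, ang)
      arcPts <- t(sapply(th, function(t0) ctr + rotateAbout(p - ctr, ax, t0)))
      out <- rbind(out, arcPts)
      dEnd <- rotateAbout(d, ax, ang)
      pEnd <- arcPts[nrow(arcPts), ]
      if (post > 0) {
        s <- seq(hUm, post, by = hUm)
        if (max(s) < post) s <- c(s, post)
        out <- rbind(out, t(sapply(s, function(si) pEnd + si * dEnd)))
      }
      out
    },
    helix = {
      R <- cl$radiusUm; cc <- cl$riseUm
      thMax <- 2 * pi * cl$turns
      dth <- hUm / sqrt(R^2 + cc^2)
      th <- seq(0, thMax, by = dth)
      if (max(th) < thMax) th <- c(th, thMax)
      cbind(cl$center[1] + cc * th,
            cl$center[2] + R * sin(th),
            cl$center[3] + R * cos(th))
    },
    sine = {
      d <- normalize(cl$direction)
      tv <- normalize(cl$transverse - sum(cl$transverse * d) * d)
      xs <- seq(0, cl$lengthUm, by = hUm / 2)
      off <- cl$amplitudeUm * sin(2 * pi * xs / cl$wavelengthUm)
      cbind(cl$start[1] + xs * d[1] + off * tv[1],
            cl$start[2] + xs * d[2] + off * tv[2],
            cl$start[3] + xs * d[3] + off * tv[3])
    },
    polyline = as.matrix(cl$points),
    randomwalk = {
      d <- normalize(cl$direction)
      h <- 2
      n <- ceiling(cl$lengthUm / h)
      out <- matrix(0, n + 1, 3)
      out[1, ] <- cl$start
      maxTurn <- cl$maxCurvature * h
      for (i in seq_len(n)) {
        ax <- normalize(cross3(d, stats::rnorm(3)))
        d <- normalize(rotateAbout(d, ax, stats::runif(1, -maxTurn, maxTurn)))
        out[i + 1, ] <- out[i, ] + h * d
      }
      out
    },
    stop("unknown centerline model: ", cl$model))
  res <- resamplePolyline(pts, hUm)
  res
}

# Distance field of one tube within its crop. Returns crop limits plus D
# (min distance to centerline) and S (arc length of the closest point).
tubeDistanceField <- function(points, s, rad, spacing, origin, shape,
                              padUm = 3) {
  # point-to-segment distance is exact for a polyline, so a ~1.5 um chord
  # resolution suffices (chord error h^2/(8*Rc) is far below voxel size)
  hSeg <- max(min(spacing) / 2, 1.5)
  rs <- resamplePolyline(points, hSeg)
  sEnd <- max(s)
  rad <- radiusAt0 <- approx(s, rad, xout = rs$s, rule = 2)$y
  points <- rs$points; s <- rs$s
  rmax <- max(rad)
  reach <- rmax + padUm
  lo <- floor((apply(points, 2, min) - reach - origin) / spacing) + 1
  hi <- ceiling((apply(points, 2, max) + reach - origin) / spacing) + 1
  lo <- pmax(lo, 1); hi <- pmin(hi, shape)
  if (any(hi < lo)) stop("tube lies entirely outside the volume")
  nd <- hi - lo + 1
  D <- array(Inf, dim = nd)
  S <- array(NA_real_, dim = nd)
  zz <- origin[1] + (seq(lo[1], hi[1]) - 1) * spacing[1]
  yy <- origin[2] + (seq(lo[2], hi[2]) - 1) * spacing[2]
  xx <- origin[3] + (seq(lo[3], hi[3]) - 1) * spacing[3]
  # fast path: a perfectly straight centerline has a closed-form distance
  p0 <- points[1, ]; pN <- points[nrow(points), ]
  dLine <- normalize(pN - p0)
  proj <- (sweep(points, 2, p0) %*% dLine)[, 1]
  perp <- points - (outer(proj, dLine) + matrix(p0, nrow(points), 3, byrow = TRUE))
  if (max(abs(perp)) < 1e-9) {
    # separable evaluation: t = (q - p0) . d and |q - p0|^2 decompose per axis
    tz <- (zz - p0[1]) * dLine[1]; ty <- (yy - p0[2]) * dLine[2]
    tx <- (xx - p0[3]) * dLine[3]
    qz <- (zz - p0[1])^2; qy <- (yy - p0[2])^2; qx <- (xx - p0[3])^2
    t <- rep(tz, times = nd[2] * nd[3]) +
      rep(rep(ty, each = nd[1]), times = nd[3]) +
      rep(tx, each = nd[1] * nd[2])
    Q2 <- rep(qz, times = nd[2] * nd[3]) +
      rep(rep(qy, each = nd[1]), times = nd[3]) +
      rep(qx, each = nd[1] * nd[2])
    tc <- pmin(pmax(t, 0), max(s))
    D <- sqrt(pmax(Q2 - 2 * tc * t + tc^2, 0))
    dim(D) <- nd; dim(tc) <- nd
    return(list(lo = lo, hi = hi, D = D, S = tc, sMax = max(s)))
  }
  # process the centerline in blocks; every voxel within reach of a block's
  # points is covered by that block's bounding box, and the global pmin over
  # blocks gives the exact distance to the full polyline
  blockLen <- 24 # um of arc per block
  n <- nrow(points)
  bStart <- 1
  while (bStart < n) {
    bEnd <- min(n, bStart + max(2, ceiling(blockLen / max(diff(s[1:2]), 1e-6))))
    idx <- bStart:bEnd
    p <- points[idx, , drop = FALSE]
    rloc <- max(rad[idx]) + padUm
    blo <- pmax(floor((apply(p, 2, min) - rloc - origin) / spacing) + 1, lo)
    bhi <- pmin(ceiling((apply(p, 2, max) + rloc - origin) / spacing) + 1, hi)
    if (all(bhi >= blo)) {
      iz <- seq(blo[1], bhi[1]); iy <- seq(blo[2], bhi[2]); ix <- seq(blo[3], bhi[3])
      grid <- cbind(
        rep(zz[iz - lo[1] + 1], times = length(iy) * length(ix)),
        rep(rep(yy[iy - lo[2] + 1], each = length(iz)), times = length(ix)),
        rep(xx[ix - lo[3] + 1], each = length(iz) * length(iy)))
      res <- distanceToPolyline(grid, p, s = s[idx])
      sub <- list(iz - lo[1] + 1, iy - lo[2] + 1, ix - lo[3] + 1)
      dOld <- D[sub[[1]], sub[[2]], sub[[3]]]
      sOld <- S[sub[[1]], sub[[2]], sub[[3]]]
      upd <- res$distance < dOld
      dOld[upd] <- res$distance[upd]
      sOld[upd] <- res$s[upd]
      D[sub[[1]], sub[[2]], sub[[3]]] <- dOld
      S[sub[[1]], sub[[2]], sub[[3]]] <- sOld
    }
    bStart <- bEnd
  }
  list(lo = lo, hi = hi, D = D, S = S, sMax = max(s))
}

inGap <- function(s, gaps) {
  if (length(gaps) == 0) return(rep(FALSE, length(s)))
  out <- rep(FALSE, length(s))
  for (g in gaps) out <- out | (s >= g[1] & s <= g[2])
  out
}

# Stamp bright spheres into a full-volume array (used for nuclei and for the
# wave phantom's staining objects). centers: n x 3 world um.
stampSpheres <- function(arr, centers, radiusUm, level, spacing, origin) {
  dm <- dim(arr)
  for (i in seq_len(nrow(centers))) {
    p <- centers[i, ]
    lo <- pmax(floor((p - radiusUm - origin) / spacing) + 1, 1)
    hi <- pmin(ceiling((p + radiusUm - origin) / spacing) + 1, dm)
    if (any(hi < lo)) next
    iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
    dz2 <- (origin[1] + (iz - 1) * spacing[1] - p[1])^2
    dy2 <- (origin[2] + (iy - 1) * spacing[2] - p[2])^2
    dx2 <- (origin[3] + (ix - 1) * spacing[3] - p[3])^2
    d2 <- outer(outer(dz2, dy2, "+"), dx2, "+")
    blk <- arr[iz, iy, ix]
    blk[d2 <= radiusUm^2] <- pmax(blk[d2 <= radiusUm^2], level)
    arr[iz, iy, ix] <- blk
  }
  arr
}

# Assemble one tube description (centerline points, s, radii) from a spec.
tubeFromSpec <- function(spec, hUm) {
  cl <- buildCenterline(spec@centerline, hUm = hUm)
  rad <- radiusAt(spec@radius, cl$s)
  list(points = cl$points, s = cl$s, rad = rad, spec = spec)
}

checkInsideBounds <- function(tube, spacing, origin, shape, label = "tube") {
  wmin <- origin
  wmax <- origin + (shape - 1) * spacing
  pts <- tube$points
  n <- nrow(pts)
  # margin to each of the 6 faces (zlo, ylo, xlo, zhi, yhi, xhi)
  margin <- cbind(sweep(pts, 2, wmin), sweep(-pts, 2, -wmax))
  tang <- rbind(pts[2, ] - pts[1, ],
                pts[pmin(1:(n - 1) + 2, n), , drop = FALSE] -
                  pts[1:(n - 1), , drop = FALSE])
  tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
  # a tube may run out through a face it is heading into (real tubules cross
  # the slab boundary); it must not graze a face sideways
  headCos <- abs(cbind(tang, tang))
  ok <- margin >= tube$rad | headCos > 0.7
  bad <- which(!apply(ok, 1, all))
  if (length(bad) > 0)
    stop(sprintf(
      "%s centerline leaves the volume laterally: point %d at (%.1f, %.1f, %.1f) um is closer to a side boundary than its radius %.1f um",
      label, bad[1], pts[bad[1], 1], pts[bad[1], 2], pts[bad[1], 3],
      tube$rad[bad[1]]))
  invisible(TRUE)
}

# Core renderer shared by all phantom constructors.
renderPhantom <- function(spec, tubes) {
  spacing <- spec@spacing; origin <- spec@origin; shape <- spec@shape
  set.seed(spec@seed)
  vol <- array(spec@intensity$background, dim = shape)
  unionMask <- array(FALSE, dim = shape)
  tubeMasks <- vector("list", length(tubes))
  fields <- vector("list", length(tubes))
  for (t in seq_along(tubes)) {
    tb <- tubes[[t]]
    checkInsideBounds(tb, spacing, origin, shape,
                      label = if (t == 1) "tube" else sprintf("branch %d", t - 1))
    fld <- tubeDistanceField(tb$points, tb$s, tb$rad, spacing, origin, shape)
    rHere <- array(radiusAt(tb$spec@radius, as.numeric(fld$S)), dim = dim(fld$D))
    # exclude voxels whose closest centerline point is an endpoint: this cuts
    # the tube flat at both ends instead of adding hemispherical caps
    mask <- fld$D <= rHere & fld$S > 1e-6 & fld$S < fld$sMax - 1e-6
    iz <- fld$lo[1]:fld$hi[1]; iy <- fld$lo[2]:fld$hi[2]; ix <- fld$lo[3]:fld$hi[3]
    im <- tb$spec@intensity
    gapped <- array(inGap(as.numeric(fld$S), tb$spec@gaps), dim = dim(fld$D))
    blk <- vol[iz, iy, ix]
    if (identical(im$model, "wall")) {
      wall <- mask & fld$D > (rHere - im$wallThicknessUm)
      lum <- mask & !wall
      fgLevel <- im$contrast * im$background
      blk[wall & !gapped] <- pmax(blk[wall & !gapped], fgLevel)
      blk[lum] <- pmax(blk[lum], im$lumen)
    } else if (identical(im$model, "solid")) {
      fgLevel <- im$contrast * im$background
      blk[mask & !gapped] <- pmax(blk[mask & !gapped], fgLevel)
    } else if (identical(im$model, "bands")) {
      # distance-banded intensities (seminiferous-style): list of
      # (innerUm, outerUm, level) relative to the local radius when
      # relative=TRUE, absolute distances otherwise
      for (bd in im$bands) {
        inner <- if (isTRUE(bd$relative)) bd$innerFrac * rHere else bd$innerUm
        outer <- if (isTRUE(bd$relative)) bd$outerFrac * rHere else bd$outerUm
        sel <- mask & fld$D > inner & fld$D <= outer & !gapped
        blk[sel] <- pmax(blk[sel], bd$level)
      }
    } else stop("unknown intensity model: ", im$model)
    vol[iz, iy, ix] <- blk
    um <- unionMask[iz, iy, ix]
    unionMask[iz, iy, ix] <- um | mask
    tubeMasks[[t]] <- new("TubuleVolumeMask", mask = mask,
                          offset = as.integer(fld$lo), spacing = spacing,
                          origin = origin, trackId = sprintf("truth_%d", t))
    fields[[t]] <- fld
  }
  list(volume = vol, unionMask = unionMask, tubeMasks = tubeMasks,
       fields = fields)
}

finishVolume <- function(vol, spec, channel) {
  if (spec@noiseSd > 0)
    vol <- pmax(vol + array(stats::rnorm(length(vol), 0, spec@noiseSd),
                            dim = dim(vol)), 0)
  voxelGrid(vol, spacing = spec@spacing, origin = spec@origin,
            channel = channel)
}

truthCenterline <- function(tube, stepUm = 1) {
  rs <- resamplePolyline(tube$points, stepUm)
  data.frame(z = rs$points[, 1], y = rs$points[, 2], x = rs$points[, 3],
             s = rs$s, radius = radiusAt(tube$spec@radius, rs$s))
}

#' Generate a tubular phantom with ground truth
#'
#' Renders the tube described by `spec` into a noisy intensity volume and
#' returns it together with the complete ground truth (centerline, radius,
#' voxel mask, planted nuclei). Wall voxels (within `wallThicknessUm` of the
#' surface) are set to `contrast x background`; the lumen is dim. With a
#' `nuclei` spec, a second DNA-like channel volume is returned with bright
#' spherical nuclei planted at the stated linear density: a fraction
#' `inLumenFraction` strictly inside the lumen, the rest outside the tube.
#'
#' @param spec a [PhantomSpec-class] from [tubePhantomSpec()].
#' @return A list with elements `volume` ([VoxelGrid-class]), `truth`
#'   ([PhantomTruth-class]) and `nucleiVolume` ([VoxelGrid-class] or NULL).
#' @export
makeTubePhantom <- function(spec) {
  hUm <- min(spec@spacing) / 4
  tube <- tubeFromSpec(spec, hUm)
  rend <- renderPhantom(spec, list(tube))
  nucleiVol <- NULL
  nucDf <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                      inLumen = logical(0), tubule = integer(0))
  if (length(spec@nuclei) > 0) {
    planted <- plantNuclei(spec, tube)
    nucDf <- planted$df
    nvol <- array(10, dim = spec@shape)
    if (nrow(nucDf) > 0)
      nvol <- stampSpheres(nvol, as.matrix(nucDf[, c("z", "y", "x")]),
                           spec@nuclei$radiusUm, 200, spec@spacing, spec@origin)
    nucleiVol <- finishVolume(nvol, spec, "nuclei")
  }
  truth <- new("PhantomTruth",
               centerline = truthCenterline(tube),
               mask = rend$unionMask, nuclei = nucDf,
               classes = data.frame(), junctions = emptyJunctions()[0, 1:5],
               tubeMasks = rend$tubeMasks)
  list(volume = finishVolume(rend$volume, spec, "carbohydrate"),
       truth = truth, nucleiVolume = nucleiVol)
}

# Plant nuclei along the tube: Poisson count at the stated linear density,
# uniform in arc length; in-lumen nuclei strictly inside the lumen, the rest
# offset outside the wall as distractors.
plantNuclei <- function(spec, tube) {
  np <- spec@nuclei
  L <- max(tube$s)
  nTot <- stats::rpois(1, np$densityPerUm * L)
  if (nTot == 0)
    return(list(df = data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                                inLumen = logical(0), tubule = integer(0))))
  sPos <- sort(stats::runif(nTot, 0.02 * L, 0.98 * L))
  inLum <- stats::runif(nTot) < np$inLumenFraction
  rs <- resamplePolyline(tube$points, 1)
  idx <- pmax(1, pmin(nrow(rs$points), round(sPos) + 1))
  ctr <- rs$points[idx, , drop = FALSE]
  rad <- radiusAt(spec@radius, sPos)
  wallTh <- spec@intensity$wallThicknessUm
  # local frame per point for the radial offset
  tang <- rs$points[pmin(idx + 1, nrow(rs$points)), , drop = FALSE] -
    rs$points[pmax(idx - 1, 1), , drop = FALSE]
  out <- matrix(0, nTot, 3)
  for (i in seq_len(nTot)) {
    tU <- normalize(tang[i, ])
    e1 <- orthoComplement(tU); e2 <- cross3(tU, e1)
    if (inLum[i]) {
      rmax <- max(rad[i] - wallTh - np$radiusUm - 0.5, 0.5)
      rho <- sqrt(stats::runif(1)) * rmax
    } else {
      rho <- rad[i] + np$radiusUm + stats::runif(1, 1, 3 * np$radiusUm)
    }
    th <- stats::runif(1, 0, 2 * pi)
    out[i, ] <- ctr[i, ] + rho * (cos(th) * e1 + sin(th) * e2)
  }
  dm <- spec@shape
  keep <- out[, 1] > spec@origin[1] + np$radiusUm &
    out[, 1] < spec@origin[1] + (dm[1] - 1) * spec@spacing[1] - np$radiusUm &
    out[, 2] > spec@origin[2] + np$radiusUm &
    out[, 2] < spec@origin[2] + (dm[2] - 1) * spec@spacing[2] - np$radiusUm &
    out[, 3] > spec@origin[3] + np$radiusUm &
    out[, 3] < spec@origin[3] + (dm[3] - 1) * spec@spacing[3] - np$radiusUm
  list(df = data.frame(z = out[keep, 1], y = out[keep, 2], x = out[keep, 3],
                       inLumen = inLum[keep],
                       tubule = ifelse(inLum[keep], 1L, NA_integer_)))
}

#' Generate a branching phantom
#'
#' Each entry of `spec@branches` attaches a child tube at arc length
#' `attachS` of the parent; if `reconnectS` is set the child's far end is
#' warped back onto the parent centerline at that arc length and the event is
#' recorded as a reconnection, not an additional branch point.
#'
#' @param spec a [PhantomSpec-class] with non-empty `branches`.
#' @return As [makeTubePhantom()]; `truth@junctions` lists one `branch` row
#'   per attachment and one `reconnection` row per reconnect.
#' @export
makeBranchingPhantom <- function(spec) {
  if (length(spec@branches) == 0) stop("spec has no branch entries")
  hUm <- min(spec@spacing) / 4
  parent <- tubeFromSpec(spec, hUm)
  rsP <- resamplePolyline(parent$points, 1)
  tubes <- list(parent)
  jn <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                   s = numeric(0), kind = character(0))
  for (b in spec@branches) {
    child <- tubeFromSpec(b$spec, hUm)
    iA <- pmax(1, pmin(nrow(rsP$points), round(b$attachS) + 1))
    target <- rsP$points[iA, ]
    shift <- target - child$points[1, ]
    child$points <- sweep(child$points, 2, shift, "+")
    jn <- rbind(jn, data.frame(z = target[1], y = target[2], x = target[3],
                               s = b$attachS, kind = "branch"))
    if (!is.null(b$reconnectS)) {
      iR <- pmax(1, pmin(nrow(rsP$points), round(b$reconnectS) + 1))
      tgtR <- rsP$points[iR, ]
      endErr <- tgtR - child$points[nrow(child$points), ]
      w <- child$s / max(child$s)
      child$points <- child$points + outer(w, endErr)
      jn <- rbind(jn, data.frame(z = tgtR[1], y = tgtR[2], x = tgtR[3],
                                 s = b$reconnectS, kind = "reconnection"))
    }
    tubes <- c(tubes, list(child))
  }
  rend <- renderPhantom(spec, tubes)
  checkBranchCollisions(rend, tubes, jn, spec)
  truth <- new("PhantomTruth",
               centerline = truthCenterline(parent),
               mask = rend$unionMask,
               nuclei = data.frame(z = numeric(0), y = numeric(0),
                                   x = numeric(0), inLumen = logical(0),
                                   tubule = integer(0)),
               classes = data.frame(), junctions = jn,
               tubeMasks = rend$tubeMasks)
  list(volume = finishVolume(rend$volume, spec, "carbohydrate"),
       truth = truth, nucleiVolume = NULL,
       childCenterlines = lapply(tubes[-1], truthCenterline))
}

# A child may touch its parent near declared junctions only; contact far from
# every junction means the requested geometry self-collides.
checkBranchCollisions <- function(rend, tubes, jn, spec) {
  if (nrow(jn) == 0) return(invisible(TRUE))
  pm <- rend$tubeMasks[[1]]
  for (t in seq_along(tubes)[-1]) {
    cm <- rend$tubeMasks[[t]]
    lo <- pmax(pm@offset, cm@offset)
    hi <- pmin(pm@offset + dim(pm@mask) - 1L, cm@offset + dim(cm@mask) - 1L)
    if (any(hi < lo)) next
    pSub <- pm@mask[(lo[1]:hi[1]) - pm@offset[1] + 1L,
                    (lo[2]:hi[2]) - pm@offset[2] + 1L,
                    (lo[3]:hi[3]) - pm@offset[3] + 1L, drop = FALSE]
    cSub <- cm@mask[(lo[1]:hi[1]) - cm@offset[1] + 1L,
                    (lo[2]:hi[2]) - cm@offset[2] + 1L,
                    (lo[3]:hi[3]) - cm@offset[3] + 1L, drop = FALSE]
    both <- which(pSub & cSub, arr.ind = TRUE)
    if (nrow(both) == 0) next
    w <- sweep(sweep(both + matrix(lo - 1, nrow(both), 3, byrow = TRUE) - 1,
                     2, spec@spacing, "*"), 2, spec@origin, "+")
    allow <- 2 * (max(radiusAt(spec@radius, jn$s)) +
                    max(tubes[[t]]$rad))
    dj <- sapply(seq_len(nrow(jn)), function(j)
      sqrt((w[, 1] - jn$z[j])^2 + (w[, 2] - jn$y[j])^2 + (w[, 3] - jn$x[j])^2))
    dj <- if (is.matrix(dj)) apply(dj, 1, min) else dj
    if (any(dj > allow))
      stop(sprintf(
        "branch %d collides with the parent %.0f um away from any declared junction",
        t - 1, max(dj)))
  }
  invisible(TRUE)
}
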