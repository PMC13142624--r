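# 2D cross-section segmentation with pluggable backends, centre-mask
# selection, second-moment ellipse geometry, and SSIM-based selection of
# diverse frames for annotation.

#' Create a segmentation model specification
#'
#' Backends:
#' \describe{
#'   \item{builtin-threshold}{Otsu threshold, hole filling, then a
#'     diameter-prior acceptance band: objects are kept only when their
#'     equivalent circular diameter lies within `bandLow`..`bandHigh` times
#'     `diameterPriorUm`. The band emulates the strong diameter-prior
#'     sensitivity of learned cell-segmentation models, which miss objects
#'     far from the configured diameter — the behaviour the troubleshooting
#'     diameter sweep exists to recover.}
#'   \item{builtin-lumen}{The same pipeline on the inverted image (captures
#'     the dim lumen disk of wall-bright tubules); components touching the
#'     raster border are discarded as background.}
#'   \item{any other key}{Looked up in the plugin registry; see
#'     [registerSegmentationBackend()].}
#' }
#'
#' @param modelId label used in tracks and logs.
#' @param backend backend key.
#' @param diameterPriorUm expected object diameter in um (> 0).
#' @param options named list of extra backend options (`bandLow`, `bandHigh`
#'   for the builtin backends).
#' @return A list of class `SegmentationModel`.
#' @export
segmentationModel <- function(modelId, backend = "builtin-threshold",
                              diameterPriorUm = 34, options = list()) {
  stopifnot(diameterPriorUm > 0)
  structure(list(modelId = modelId, backend = backend,
                 diameterPriorUm = diameterPriorUm,
                 options = modifyList(list(bandLow = 0.45, bandHigh = 2.2,
                                           eccReject = 0.9),
                                      options)),
            class = "SegmentationModel")
}

#' @export
print.SegmentationModel <- function(x, ...) {
  cat(sprintf("SegmentationModel '%s' (backend %s, diameter prior %.1f um)\n",
              x$modelId, x$backend, x$diameterPriorUm))
  invisible(x)
}

backendRegistry <- new.env(parent = emptyenv())

#' Register a plugin segmentation backend
#'
#' The plugin contract: `fun(pixels, diameterPriorPx, options)` receives the
#' raw raster (matrix) and the diameter prior in pixels, and returns an
#' integer label matrix (0 = background).
#'
#' @param key backend key referenced by [segmentationModel()].
#' @param fun the backend function.
#' @return `key`, invisibly.
#' @export
registerSegmentationBackend <- function(key, fun) {
  assign(key, fun, envir = backendRegistry)
  invisible(key)
}

relabel <- function(lab) {
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0) return(lab)
  out <- array(0L, dim = dim(lab))
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

builtinSegment <- function(px, dpPx, opts, invert = FALSE, oob = NULL) {
  if (is.null(oob)) oob <- array(FALSE, dim = dim(px))
  inb <- px[!oob]
  if (length(inb) == 0) return(array(0L, dim = dim(px)))
  rng <- range(inb)
  if (diff(rng) < 1e-9) return(array(0L, dim = dim(px)))
  # threshold statistics over in-bounds pixels only; out-of-bounds pixels are
  # defined background (they carry no signal, only padding zeros)
  norm <- pmin(pmax((px - rng[1]) / diff(rng), 0), 1)
  if (invert) norm <- 1 - norm
  thr <- EBImage::otsu(EBImage::Image(
    matrix(norm[!oob], nrow = 1)))
  bin <- norm > thr & !oob
  if (invert) {
    # inverted images: components touching the raster border or adjacent to
    # out-of-bounds padding are background, and must go before hole filling
    # (the background ring would otherwise swallow the lumen as its "hole")
    lab0 <- array(as.integer(EBImage::bwlabel(EBImage::Image(bin))),
                  dim = dim(px))
    oobAdj <- oob
    if (any(oob)) {
      oobAdj[-1, ] <- oobAdj[-1, ] | oob[-nrow(oob), ]
      oobAdj[-nrow(oob), ] <- oobAdj[-nrow(oob), ] | oob[-1, ]
      oobAdj[, -1] <- oobAdj[, -1] | oob[, -ncol(oob)]
      oobAdj[, -ncol(oob)] <- oobAdj[, -ncol(oob)] | oob[, -1]
    }
    bg <- unique(c(lab0[1, ], lab0[nrow(lab0), ], lab0[, 1],
                   lab0[, ncol(lab0)], lab0[oobAdj]))
    bin <- bin & !(lab0 %in% bg[bg > 0])
    dim(bin) <- dim(px)
  }
  bin <- EBImage::fillHull(EBImage::Image(bin)) > 0.5
  lab <- EBImage::bwlabel(EBImage::Image(bin))
  lab <- array(as.integer(lab), dim = dim(px))
  if (max(lab) == 0) return(lab)
  areas <- tabulate(lab[lab > 0])
  dEq <- 2 * sqrt(areas / pi)                # px units
  keep <- dEq >= opts$bandLow * dpPx & dEq <= opts$bandHigh * dpPx
  # cell-like shape prior: learned cell segmenters handle round-to-elliptical
  # objects and fail on highly elongated ones; the builtin backends mirror
  # that so orientation errors surface the way they do with learned models
  if (!is.null(opts$eccReject) && is.finite(opts$eccReject)) {
    for (k in which(keep)) {
      e <- tryCatch(fitEllipse(lab == k)$eccentricity, error = function(e) 1)
      if (e > opts$eccReject) keep[k] <- FALSE
    }
  }
  lab[!keep[pmax(lab, 1)] | lab == 0] <- 0L
  relabel(lab)
}

#' Segment a plane image
#'
#' @param image a [PlaneImage-class].
#' @param model a `SegmentationModel`.
#' @param diameterPriorUm overrides the model's diameter prior (used by the
#'   troubleshooting diameter sweep).
#' @return A [SegmentationOutcome-class]; `success` is FALSE when no object
#'   was found. An unavailable plugin backend raises an error (a declared
#'   failure, distinct from "no mask found").
#' @export
segmentPlane <- function(image, model, diameterPriorUm = NULL) {
  dp <- if (is.null(diameterPriorUm)) model$diameterPriorUm else diameterPriorUm
  dpPx <- dp / image@plane@pitch
  px <- image@pixels
  lab <- switch(model$backend,
    "builtin-threshold" = builtinSegment(px, dpPx, model$options,
                                         invert = FALSE, oob = image@oob),
    "builtin-lumen" = builtinSegment(px, dpPx, model$options,
                                     invert = TRUE, oob = image@oob),
    {
      if (!exists(model$backend, envir = backendRegistry))
        stop("segmentation backend '", model$backend,
             "' is not registered (plugin unavailable)")
      fun <- get(model$backend, envir = backendRegistry)
      lab0 <- fun(px, dpPx, model$options)
      relabel(array(as.integer(lab0), dim = dim(px)))
    })
  new("SegmentationOutcome", labels = lab, modelId = model$modelId,
      success = max(lab) > 0)
}

# Mask geometry: centroid, area, equivalent diameter, second-moment ellipse.
maskGeometry <- function(mask, plane, modelId = "") {
  idx <- which(mask, arr.ind = TRUE)
  npx <- nrow(idx)
  pitch <- plane@pitch
  ctrPx <- colMeans(idx)                     # (row, col)
  n <- nrow(mask)
  ctrWorld <- planePixelToWorld(plane, ctrPx[1], ctrPx[2], n = n)[1, ]
  A <- npx * pitch^2
  dEq <- 2 * sqrt(A / pi)
  ell <- fitEllipse(mask, pitch)
  new("CrossSectionMask", mask = mask, plane = plane,
      centroidPx = as.numeric(ctrPx), centroidWorld = as.numeric(ctrWorld),
      areaUm2 = A, equivDiameterUm = dEq, ellipse = ell, modelId = modelId)
}

#' Fit the second-moment ellipse of a binary mask
#'
#' The ellipse with the same second central moments as the solid mask:
#' semi-axes `2*sqrt(eigenvalues)` of the pixel covariance (scaled to um),
#' orientation phi of the major axis measured from the plane's u axis, and
#' eccentricity `sqrt(1 - (minor/major)^2)`.
#'
#' @param mask logical matrix (row ~ v axis, column ~ u axis).
#' @param pitch pixel pitch in um.
#' @return list(major, minor, phi, eccentricity).
#' @export
fitEllipse <- function(mask, pitch = 1) {
  idx <- which(mask, arr.ind = TRUE)
  npx <- nrow(idx)
  if (npx < 5) {
    d <- 2 * sqrt(npx / pi) * pitch
    return(list(major = d / 2, minor = d / 2, phi = 0, eccentricity = 0))
  }
  uu <- idx[, 2] * pitch                     # along u (columns)
  vv <- idx[, 1] * pitch                     # along v (rows)
  cu <- mean(uu); cv <- mean(vv)
  m20r <- mean((uu - cu)^2)
  m02r <- mean((vv - cv)^2)
  m11 <- mean((uu - cu) * (vv - cv))
  # collinearity is judged on the raw pixel-centre moments, before the pixel
  # self-moment regularizes the minor axis
  rawDisc <- sqrt(max((m20r + m02r)^2 / 4 - (m20r * m02r - m11^2), 0))
  if ((m20r + m02r) / 2 - rawDisc <= 1e-12)
    stop("degenerate (collinear) mask: ellipse fit undefined")
  m20 <- m20r + pitch^2 / 12                 # add pixel self-moment
  m02 <- m02r + pitch^2 / 12
  tr <- m20 + m02
  det <- m20 * m02 - m11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  major <- 2 * sqrt(l1); minor <- 2 * sqrt(l2)
  phi <- 0.5 * atan2(2 * m11, m20 - m02)
  list(major = major, minor = minor, phi = phi,
       eccentricity = sqrt(max(1 - (minor / major)^2, 0)))
}

#' Select the mask overlapping the plane centre
#'
#' @param outcome a [SegmentationOutcome-class].
#' @param image the segmented [PlaneImage-class].
#' @return A [CrossSectionMask-class], or NULL when the centre pixel is
#'   background (absence is a valid result).
#' @export
selectCenterMask <- function(outcome, image) {
  lab <- outcome@labels
  n <- nrow(lab)
  c0 <- round((n + 1) / 2)
  k <- lab[c0, c0]
  if (k == 0) return(NULL)
  maskGeometry(lab == k, image@plane, modelId = outcome@modelId)
}

# ---- SSIM-based training-frame selection --------------------------------

meanDownsample2 <- function(m) {
  n <- dim(m) %/% 2
  if (any(n < 1)) return(m)
  m <- m[seq_len(2 * n[1]), seq_len(2 * n[2]), drop = FALSE]
  0.25 * (m[seq(1, 2 * n[1], 2), seq(1, 2 * n[2], 2), drop = FALSE] +
          m[seq(2, 2 * n[1], 2), seq(1, 2 * n[2], 2), drop = FALSE] +
          m[seq(1, 2 * n[1], 2), seq(2, 2 * n[2], 2), drop = FALSE] +
          m[seq(2, 2 * n[1], 2), seq(2, 2 * n[2], 2), drop = FALSE])
}

ssimSingle <- function(x, y, dynamicRange) {
  C1 <- (0.01 * dynamicRange)^2; C2 <- (0.03 * dynamicRange)^2
  if (min(dim(x)) >= 16) {
    g <- outer(stats::dnorm(-5:5, sd = 1.5), stats::dnorm(-5:5, sd = 1.5))
    g <- g / sum(g)
    f <- function(m) as.matrix(EBImage::filter2(EBImage::Image(m), g))
    mx <- f(x); my <- f(y)
    sxx <- f(x * x) - mx^2; syy <- f(y * y) - my^2; sxy <- f(x * y) - mx * my
    mean(((2 * mx * my + C1) * (2 * sxy + C2)) /
           ((mx^2 + my^2 + C1) * (sxx + syy + C2)))
  } else {
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    ((2 * mx * my + C1) * (2 * cxy + C2)) /
      ((mx^2 + my^2 + C1) * (vx + vy + C2))
  }
}

#' Multi-scale structural similarity of two frames
#'
#' Mean windowed SSIM averaged over three dyadic scales.
#'
#' @param x,y numeric matrices of identical shape.
#' @param nScales number of dyadic scales.
#' @return SSIM in (-1, 1]; 1 for identical frames.
#' @export
msSsim <- function(x, y, nScales = 3) {
  stopifnot(all(dim(x) == dim(y)))
  dr <- max(max(x), max(y)) - min(min(x), min(y))
  if (dr < 1e-12) return(1)
  vals <- numeric(0)
  for (sc in seq_len(nScales)) {
    vals <- c(vals, ssimSingle(x, y, dr))
    if (min(dim(x)) < 8) break
    x <- meanDownsample2(x); y <- meanDownsample2(y)
  }
  mean(vals)
}

#' Select diverse frames for annotation along a centerline
#'
#' Greedy scan over ordered frames: the first frame is always kept; a later
#' frame is kept only when (1 - SSIM vs the previously kept frame) >= alpha,
#' (1 - mean SSIM vs all kept frames) >= beta, and it is at least
#' `minInterval` frames beyond the last kept one.
#'
#' @param planes list of [PlaneImage-class] or numeric matrices, ordered
#'   along a centerline.
#' @param params a [FrameSelectionParams-class].
#' @return Integer indices of the kept frames (empty for empty input).
#' @export
selectTrainingFrames <- function(planes, params) {
  if (length(planes) == 0) return(integer(0))
  mats <- lapply(planes, function(p) if (is(p, "PlaneImage")) p@pixels else p)
  kept <- 1L
  lastKept <- 1L
  for (i in seq_along(mats)[-1]) {
    if (i - lastKept < params@minInterval) next
    localChange <- 1 - msSsim(mats[[i]], mats[[lastKept]])
    if (localChange < params@alpha) next
    globalChange <- 1 - mean(vapply(kept, function(k)
      msSsim(mats[[i]], mats[[k]]), numeric(1)))
    if (globalChange < params@beta) next
    kept <- c(kept, i)
    lastKept <- i
  }
  kept
}
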