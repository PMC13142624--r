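# Spatially resolved morphometrics (length, diameter, discrete curvature and
# torsion), nephron loop-type classification, per-segment summaries, and
# tracking-quality evaluation against a ground-truth centerline.

#' Morphometric profiles along a centerline
#'
#' The centerline is resampled at a uniform arc-length step and lightly
#' smoothed with a 3-point moving average to suppress segmentation jitter.
#' Curvature is estimated from the circumradius of consecutive point triples
#' (kappa = 1/R_circ); torsion from the signed dihedral angle between
#' consecutive osculating planes divided by the arc step. Node diameters are
#' linearly interpolated onto the grid.
#'
#' @param track a [Track-class], or an n x 3 matrix of centerline points
#'   (diameter then reported as NA).
#' @param stepUm resampling step (um).
#' @param smooth apply the 3-point moving average (default TRUE).
#' @return data.frame(s, diameter, curvature, torsion); curvature in 1/um
#'   (>= 0), torsion in 1/um (signed), NA at the ends where the stencils are
#'   undefined.
#' @export
morphometricProfiles <- function(track, stepUm = 5, smooth = TRUE) {
  if (is(track, "Track")) {
    pts <- as.matrix(track@nodes[, c("z", "y", "x")])
    sNode <- track@nodes$s
    dNode <- track@nodes$diameter
  } else {
    pts <- as.matrix(track)
    sNode <- NULL; dNode <- NULL
  }
  if (nrow(pts) < 4) stop("morphometric profiles need at least 4 points")
  rs <- resamplePolyline(pts, stepUm)
  p <- rs$points
  n <- nrow(p)
  if (smooth && n >= 3) {
    sm <- p
    sm[2:(n - 1), ] <- (p[1:(n - 2), ] + p[2:(n - 1), ] + p[3:n, ]) / 3
    p <- sm
  }
  kappa <- rep(NA_real_, n)
  tau <- rep(NA_real_, n)
  binorm <- matrix(NA_real_, n, 3)
  for (i in 2:(n - 1)) {
    a <- p[i - 1, ]; b <- p[i, ]; c <- p[i + 1, ]
    ab <- b - a; bc <- c - b; ac <- c - a
    cr <- cross3(ab, ac)
    den <- vecNorm(ab) * vecNorm(bc) * vecNorm(ac)
    area2 <- vecNorm(cr)
    kappa[i] <- if (den < 1e-12) 0 else 2 * area2 / den
    if (area2 > 1e-12) binorm[i, ] <- cr / area2
  }
  h <- mean(diff(rs$s))
  for (i in 3:(n - 1)) {
    b1 <- binorm[i - 1, ]; b2 <- binorm[i, ]
    if (anyNA(b1) || anyNA(b2)) { tau[i] <- 0; next }
    tvec <- normalize(p[i + 1, ] - p[i - 1, ])
    tau[i] <- atan2(sum(cross3(b1, b2) * tvec), sum(b1 * b2)) / h
  }
  diameter <- if (is.null(sNode)) rep(NA_real_, n) else {
    ok <- !is.na(dNode)
    if (sum(ok) >= 2) approx(sNode[ok], dNode[ok], xout = rs$s, rule = 2)$y
    else rep(NA_real_, n)
  }
  data.frame(s = rs$s, diameter = diameter, curvature = kappa, torsion = tau)
}

#' Classify a nephron as short-loop or long-loop
#'
#' Two rules, reported together when both are computable: the length rule
#' (thin-limb length below the threshold, default 1400 um, means short-loop)
#' and the region rule (any node labelled inner medulla means long-loop).
#'
#' @param thinLimbLengthUm thin-limb length (um), or NA.
#' @param regionLabels character vector of per-node region labels, or NULL.
#' @param thresholdUm length-rule threshold (um).
#' @param imLabel the label identifying the inner medulla.
#' @return list(class, rule, byLength, byRegion); `class` is "SLN" or "LLN"
#'   (region rule preferred when the two disagree, since inner-medulla entry
#'   is definitional).
#' @export
classifyLoopType <- function(thinLimbLengthUm = NA, regionLabels = NULL,
                             thresholdUm = 1400, imLabel = "IM") {
  byLength <- if (!is.na(thinLimbLengthUm))
    if (thinLimbLengthUm < thresholdUm) "SLN" else "LLN" else NA_character_
  byRegion <- if (!is.null(regionLabels))
    if (any(regionLabels == imLabel)) "LLN" else "SLN" else NA_character_
  if (is.na(byLength) && is.na(byRegion))
    stop("need a thin-limb length or region labels to classify loop type")
  cls <- if (!is.na(byRegion)) byRegion else byLength
  rule <- if (!is.na(byRegion) && !is.na(byLength)) "both"
          else if (!is.na(byRegion)) "region" else "length"
  list(class = cls, rule = rule, byLength = byLength, byRegion = byRegion)
}

#' Summarise morphometrics per annotated segment
#'
#' @param profile a data.frame from [morphometricProfiles()].
#' @param annotation data.frame(sStart, sEnd, label) of non-overlapping
#'   arc-length intervals (e.g. PCT / thin_limb / thick_limb).
#' @return data.frame with one row per non-empty interval: label, length,
#'   mean and SD of diameter, curvature and torsion.
#' @export
segmentSummary <- function(profile, annotation) {
  if (nrow(annotation) == 0)
    return(data.frame(label = character(0), lengthUm = numeric(0),
                      meanDiameter = numeric(0), sdDiameter = numeric(0),
                      meanCurvature = numeric(0), sdCurvature = numeric(0),
                      meanTorsion = numeric(0), sdTorsion = numeric(0)))
  out <- NULL
  for (i in seq_len(nrow(annotation))) {
    sel <- profile$s >= annotation$sStart[i] & profile$s <= annotation$sEnd[i]
    if (sum(sel) == 0) {
      warning("empty interval '", annotation$label[i], "' excluded")
      next
    }
    pr <- profile[sel, ]
    out <- rbind(out, data.frame(
      label = annotation$label[i],
      lengthUm = annotation$sEnd[i] - annotation$sStart[i],
      meanDiameter = mean(pr$diameter, na.rm = TRUE),
      sdDiameter = sd(pr$diameter, na.rm = TRUE),
      meanCurvature = mean(pr$curvature, na.rm = TRUE),
      sdCurvature = sd(pr$curvature, na.rm = TRUE),
      meanTorsion = mean(pr$torsion, na.rm = TRUE),
      sdTorsion = sd(pr$torsion, na.rm = TRUE),
      stringsAsFactors = FALSE))
  }
  if (is.null(out)) out <- segmentSummary(profile, annotation[0, ])
  out
}

#' Evaluate tracking against a ground-truth centerline
#'
#' Runs the tracker from the truth start, detects the first node that
#' deviates from the truth centerline by more than the threshold (or a
#' stall/flag), counts a break, restarts tracking from the point of
#' deviation, and repeats until the truth end is reached. The deviation
#' threshold defaults to twice the local truth diameter.
#'
#' @param volume a [VoxelGrid-class].
#' @param truthCenterline data.frame(z, y, x, s, radius) as produced by the
#'   phantom generator.
#' @param config a [TrackingConfig-class].
#' @param models segmentation model suite.
#' @param deviationThresholdUm fixed threshold (um), or NULL for 2x the
#'   local truth diameter.
#' @param maxBreaks restart cap.
#' @return list(breaks, uninterruptedLengthsUm, tracks).
#' @export
evaluateTracking <- function(volume, truthCenterline,
                             config = trackingConfig(),
                             models = list(segmentationModel("wall")),
                             deviationThresholdUm = NULL, maxBreaks = 50) {
  tc <- truthCenterline
  if (nrow(tc) < 2) stop("empty ground-truth centerline")
  truthPts <- as.matrix(tc[, c("z", "y", "x")])
  # clip truth to the volume (phantom tubes may run out through a face)
  b <- worldBounds(volume)
  inb <- truthPts[, 1] >= b$lo[1] & truthPts[, 1] <= b$hi[1] &
         truthPts[, 2] >= b$lo[2] & truthPts[, 2] <= b$hi[2] &
         truthPts[, 3] >= b$lo[3] & truthPts[, 3] <= b$hi[3]
  tc <- tc[inb, ]; truthPts <- truthPts[inb, , drop = FALSE]
  L <- max(tc$s)
  thresholdAt <- function(s) {
    if (!is.null(deviationThresholdUm)) return(deviationThresholdUm)
    4 * approx(tc$s, tc$radius, xout = pmin(pmax(s, min(tc$s)), L), rule = 2)$y
  }
  seedAt <- function(s) {
    i <- which.min(abs(tc$s - s))
    j <- which.min(abs(tc$s - (s + max(diff(tc$s)[1], 1) * 5)))
    if (j <= i) j <- min(i + 1, nrow(tc))
    rbind(truthPts[i, ], truthPts[j, ])
  }
  breaks <- 0L
  lengths <- numeric(0)
  tracks <- list()
  sStart <- min(tc$s)
  endMargin <- max(thresholdAt(L), 3 * max(diff(tc$s)))
  while (sStart < L - endMargin && breaks < maxBreaks) {
    tr <- trackTubule(volume, seedAt(sStart), config, models,
                      id = sprintf("eval_%d", length(tracks) + 1))
    tracks[[length(tracks) + 1]] <- tr
    nd <- tr@nodes
    proj <- distanceToPolyline(as.matrix(nd[, c("z", "y", "x")]),
                               truthPts, s = tc$s)
    dev <- proj$distance > thresholdAt(proj$s)
    firstBad <- if (any(dev)) which(dev)[1] else NA
    lastGood <- if (is.na(firstBad)) nrow(nd) else firstBad - 1
    sReached <- if (lastGood >= 1) max(proj$s[seq_len(lastGood)], sStart)
                else sStart
    lengths <- c(lengths, max(sReached - sStart, 0))
    finished <- is.na(firstBad) && sReached >= L - endMargin
    if (finished) break
    breaks <- breaks + 1L
    # restart from the point of deviation; force forward progress if stuck
    sNext <- max(sReached, sStart + max(thresholdAt(sStart), 10))
    sStart <- sNext
  }
  list(breaks = breaks, uninterruptedLengthsUm = lengths, tracks = tracks)
}
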