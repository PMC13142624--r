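# The core engine: stepwise vector tracking with adaptive parameters,
# rotational search, two-stage troubleshooting with multi-hypothesis
# consensus and model switching, stall detection and flagging.

#' Compute adaptive runtime parameters from recent diameters
#'
#' The running-average diameter d' is the mean of up to `window` most recent
#' cross-section diameters, clamped to the physiological bounds; the node
#' step size S = round(d'/k_step), the segmentation diameter jitter
#' J = round(d'/k_jitter) and the plane side length D = round(d' * k_dim)
#' derive from it. With no history d' is the configured initial diameter.
#'
#' @param recentDiameters numeric vector of recent node diameters (um);
#'   may be empty.
#' @param config a [TrackingConfig-class].
#' @return list(S, J, D, dPrime), all in um.
#' @examples
#' updateAdaptiveParams(numeric(0), trackingConfig())  # d' = 34: S=7 J=11 D=85
#' @export
updateAdaptiveParams <- function(recentDiameters, config) {
  d <- recentDiameters[!is.na(recentDiameters)]
  dPrime <- if (length(d) == 0) config@dInit
            else mean(utils::tail(d, config@window))
  dPrime <- min(max(dPrime, config@dMin), config@dMax)
  list(S = round(dPrime / config@kStep),
       J = round(dPrime / config@kJitter),
       D = round(dPrime * config@kDim),
       dPrime = dPrime)
}

worldBounds <- function(volume) {
  dm <- dim(volume@intensities)
  list(lo = volume@origin, hi = volume@origin + (dm - 1) * volume@spacing)
}

insideWorld <- function(p, bounds) {
  all(p >= bounds$lo) && all(p <= bounds$hi)
}

planePitch <- function(volume) min(volume@spacing[2:3])

#' Rotational search for the roundest cross-section
#'
#' Invoked when the segmented cross-section is eccentric (a possible bend or
#' local orientation error). The plane is rotated about the in-plane minor
#' axis of the fitted ellipse, r = -sin(phi) u + cos(phi) v, over
#' -rotationRange..+rotationRange degrees in rotationStep increments; each
#' candidate is re-segmented and the minimum-eccentricity candidate wins
#' (ties broken toward the smallest rotation angle). Its normal becomes the
#' new forward direction.
#'
#' @param volume a [VoxelGrid-class].
#' @param plane the current [OrientedPlane-class].
#' @param mask the eccentric [CrossSectionMask-class] that triggered the
#'   search.
#' @param model the current segmentation model.
#' @param diameterPriorUm current d'.
#' @param config a [TrackingConfig-class].
#' @return list(plane, mask, angle) for the winning candidate, or NULL when
#'   no candidate produced a centre mask.
#' @export
rotationalSearch <- function(volume, plane, mask, model, diameterPriorUm,
                             config) {
  phi <- mask@ellipse$phi
  r <- normalize(-sin(phi) * plane@u + cos(phi) * plane@v)
  angles <- seq(-config@rotationRange, config@rotationRange,
                by = config@rotationStep)
  angles <- angles[order(abs(angles), angles)]   # tie-break: smallest |angle|
  best <- NULL
  for (ang in angles) {
    th <- ang * pi / 180
    nNew <- normalize(rotateAbout(plane@normal, r, th))
    fr <- transportFrame(plane@u, plane@v, plane@normal, nNew)
    cand <- new("OrientedPlane", center = plane@center, normal = nNew,
                u = fr$u, v = fr$v, side = plane@side, pitch = plane@pitch)
    img <- samplePlane(volume, cand)
    out <- segmentPlane(img, model, diameterPriorUm = diameterPriorUm)
    m <- selectCenterMask(out, img)
    if (is.null(m)) next
    e <- m@ellipse$eccentricity
    if (is.null(best) || e < best$ecc - 1e-12) {
      best <- list(plane = cand, mask = m, angle = ang, ecc = e)
    }
  }
  best
}

#' Consensus over multi-hypothesis slab segmentations
#'
#' Per-pixel majority vote, taken slice by slice over the hypotheses that
#' found anything on that slice (a hypothesis with no objects on a slice
#' abstains there), followed by a depth-consistency rule: the consensus is
#' restricted to the 26-connected 3D component that contains the
#' target-plane centre and spans at least half the slab depth. Its
#' target-plane cross-section is returned.
#'
#' @param hypothesisLabelSlabs list of 3D arrays (rows, cols, depth) of
#'   labels or logicals; identical geometry required.
#' @param targetPlaneIndex slice index of the target plane (default 1).
#' @return Logical matrix of the consensus cross-section, or NULL when no
#'   component satisfies the rule.
#' @export
consensusFromHypotheses <- function(hypothesisLabelSlabs, targetPlaneIndex = 1) {
  if (length(hypothesisLabelSlabs) < 2)
    stop("need at least 2 hypotheses of identical slab geometry")
  dims <- lapply(hypothesisLabelSlabs, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("hypothesis slabs differ in geometry")
  bins <- lapply(hypothesisLabelSlabs, function(h) h > 0)
  d <- dim(bins[[1]])
  cons <- array(FALSE, dim = d)
  for (k in seq_len(d[3])) {
    active <- Filter(function(b) any(b[, , k]), bins)
    if (length(active) == 0) next
    votes <- Reduce(`+`, lapply(active, function(b) b[, , k] * 1L))
    cons[, , k] <- votes >= length(active) / 2
  }
  if (!any(cons)) return(NULL)
  lab <- labelComponents(cons, full = TRUE)
  d <- dim(lab)
  c0 <- round((d[1] + 1) / 2)
  centerLab <- lab[c0, c0, targetPlaneIndex]
  if (centerLab == 0) return(NULL)
  comp <- lab == centerLab
  span <- sum(apply(comp, 3, any))
  if (span < d[3] / 2) return(NULL)
  comp[, , targetPlaneIndex]
}

# Build one hypothesis slab: segment every slice of the local volume with the
# given model and diameter prior, binarized over all objects.
hypothesisSlab <- function(slab, model, diameterPriorUm) {
  arr <- array(0L, dim = c(dim(slab[[1]]@pixels), length(slab)))
  for (j in seq_along(slab)) {
    out <- segmentPlane(slab[[j]], model, diameterPriorUm = diameterPriorUm)
    arr[, , j] <- out@labels
  }
  arr
}

maskIoU2d <- function(a, b) {
  inter <- sum(a & b); un <- sum(a | b)
  if (un == 0) return(0)
  inter / un
}

# Centre-overlapping 2D component of a labelled slice.
centerComponent2d <- function(lab) {
  n <- nrow(lab)
  c0 <- round((n + 1) / 2)
  k <- lab[c0, c0]
  if (k == 0) return(NULL)
  lab == k
}

#' Two-stage troubleshooting with diameter sweep and model switching
#'
#' Stage 1 applies the current model to a local slab (depth `tsDepth` slices,
#' target plane first) over the diameter sweep d', d'-J, d'+J and takes the
#' consensus. If that fails, stage 2 repeats the sweep across the full model
#' suite. On success the hypothesis whose target-plane centre mask agrees
#' best (IoU) with the consensus supplies the adopted model and diameter
#' (ties broken toward the incumbent model, then the larger IoU denominator).
#'
#' @param volume a [VoxelGrid-class].
#' @param plane the failing target [OrientedPlane-class].
#' @param models named list of segmentation models (the suite).
#' @param incumbentId modelId currently in use.
#' @param dPrime,J current runtime diameter and jitter (um).
#' @param config a [TrackingConfig-class].
#' @return list(mask = [CrossSectionMask-class], modelId, adoptedDiameter,
#'   stage), or NULL when both stages fail.
#' @export
troubleshoot <- function(volume, plane, models, incumbentId, dPrime, J,
                         config) {
  slab <- extractLocalSlab(volume, plane, config@tsDepth)
  diams <- unique(pmax(c(dPrime, dPrime - J, dPrime + J), config@dMin))
  incumbent <- models[[match(incumbentId,
                             vapply(models, `[[`, "", "modelId"))]]
  stages <- list(list(models = list(incumbent), stage = 1L),
                 list(models = models, stage = 2L))
  for (st in stages) {
    hyps <- list(); meta <- list()
    for (m in st$models) for (dp in diams) {
      hyps[[length(hyps) + 1]] <- hypothesisSlab(slab, m, dp)
      meta[[length(meta) + 1]] <- list(modelId = m$modelId, dp = dp)
    }
    cons <- consensusFromHypotheses(hyps, targetPlaneIndex = 1)
    if (is.null(cons) || !any(cons)) next
    # score each hypothesis's target-plane centre mask against the consensus
    best <- NULL
    for (h in seq_along(hyps)) {
      cm <- centerComponent2d(hyps[[h]][, , 1])
      if (is.null(cm)) next
      iou <- maskIoU2d(cm, cons)
      denom <- sum(cm | cons)
      isIncumbent <- meta[[h]]$modelId == incumbentId
      better <- is.null(best) || iou > best$iou + 1e-12 ||
        (abs(iou - best$iou) <= 1e-12 &&
           ((isIncumbent && !best$isIncumbent) ||
              (isIncumbent == best$isIncumbent && denom > best$denom)))
      if (better)
        best <- list(h = h, iou = iou, denom = denom,
                     isIncumbent = isIncumbent)
    }
    if (is.null(best)) next
    mask <- maskGeometry(cons, plane, modelId = meta[[best$h]]$modelId)
    return(list(mask = mask, modelId = meta[[best$h]]$modelId,
                adoptedDiameter = meta[[best$h]]$dp, stage = st$stage))
  }
  NULL
}

newFlag <- function(id, nodeIndex, reason, rp) {
  data.frame(trackId = id, nodeIndex = nodeIndex, reason = reason,
             S = rp$S, J = rp$J, D = rp$D, dPrime = rp$dPrime,
             stringsAsFactors = FALSE)
}

#' Track one tubule from a seed pair
#'
#' Stepwise vector tracking: the forward direction is estimated from the two
#' most recent centerline nodes, the next node is proposed one adaptive step
#' S ahead, an orthogonal plane of side D is sampled and segmented, and the
#' node is repositioned to the centroid of the centre-overlapping mask.
#' Eccentric masks trigger rotational search; segmentation failures trigger
#' the two-stage troubleshooting module; if every recovery fails the track
#' is flagged into the correction queue. Tracking ends at the volume
#' boundary, on a stall, at a declared stop point, on merging with an
#' existing track's centerline, or after `maxSteps`.
#'
#' @param volume a [VoxelGrid-class].
#' @param seeds 2 x 3 matrix of world (z, y, x) um seed points; the initial
#'   direction is seed2 - seed1.
#' @param config a [TrackingConfig-class].
#' @param models named list of segmentation models; the first is the initial
#'   model.
#' @param stopPoints optional n x 3 matrix; arriving within
#'   `mergeToleranceUm` of one completes the track.
#' @param existingTracks optional list of [Track-class]; arriving within
#'   `mergeToleranceUm` of one terminates with status `terminated_merge`.
#' @param id track identifier.
#' @return A [Track-class].
#' @export
trackTubule <- function(volume, seeds, config = trackingConfig(),
                        models = list(segmentationModel("wall")),
                        stopPoints = NULL, existingTracks = list(),
                        id = "track_1") {
  seeds <- matrix(as.numeric(seeds), ncol = 3)
  if (nrow(seeds) != 2) stop("seeds must be a 2 x 3 matrix")
  bounds <- worldBounds(volume)
  if (!insideWorld(seeds[1, ], bounds) || !insideWorld(seeds[2, ], bounds))
    stop("seeds must lie inside the volume")
  if (vecNorm(seeds[2, ] - seeds[1, ]) < 1e-9)
    stop("seed points are coincident")
  existingPolys <- lapply(existingTracks, function(tr)
    as.matrix(tr@nodes[, c("z", "y", "x")]))

  forward <- normalize(seeds[2, ] - seeds[1, ])
  u <- orthoComplement(forward); v <- cross3(forward, u)
  pitch <- planePitch(volume)
  currentModelId <- models[[1]]$modelId
  pos <- list(seeds[1, ], seeds[2, ])
  s <- c(0, vecNorm(seeds[2, ] - seeds[1, ]))
  diamNodes <- c(NA_real_, NA_real_)
  modelCol <- c(currentModelId, currentModelId)
  rsCol <- c(FALSE, FALSE); tsCol <- c(FALSE, FALSE); manCol <- c(FALSE, FALSE)
  masks <- list(NULL, NULL)
  diamWindow <- numeric(0)
  status <- "active"
  flags <- emptyFlags()
  log <- list()

  modelById <- function(mid) models[[match(mid, vapply(models, `[[`, "", "modelId"))]]

  for (step in seq_len(config@maxSteps)) {
    rp <- if (config@enableAP) updateAdaptiveParams(diamWindow, config)
          else updateAdaptiveParams(numeric(0), config)
    propose <- pos[[length(pos)]] + rp$S * forward
    if (!insideWorld(propose, bounds)) { status <- "terminated_boundary"; break }
    plane <- new("OrientedPlane", center = propose, normal = forward,
                 u = u, v = v, side = rp$D, pitch = pitch)
    img <- samplePlane(volume, plane)
    out <- segmentPlane(img, modelById(currentModelId),
                        diameterPriorUm = rp$dPrime)
    mask <- selectCenterMask(out, img)
    usedRS <- FALSE; usedTS <- FALSE
    if (!is.null(mask) &&
        mask@ellipse$eccentricity >= config@eccentricityTrigger) {
      # an eccentric cross-section signals a bend or orientation error;
      # rotational search re-orients, otherwise it counts as a failed
      # segmentation and escalates to troubleshooting
      if (config@enableRS) {
        rs <- rotationalSearch(volume, plane, mask, modelById(currentModelId),
                               rp$dPrime, config)
        if (!is.null(rs)) {
          plane <- rs$plane; mask <- rs$mask; usedRS <- TRUE
          log[[length(log) + 1]] <- list(step = step, module = "RS",
                                         angle = rs$angle)
        } else {
          mask <- NULL   # escalate to troubleshooting
        }
      } else {
        mask <- NULL
      }
    }
    adoptedDiameter <- NULL
    if (is.null(mask) && config@enableTS) {
      ts <- troubleshoot(volume, plane, models, currentModelId,
                         rp$dPrime, rp$J, config)
      if (!is.null(ts)) {
        mask <- ts$mask
        currentModelId <- ts$modelId
        adoptedDiameter <- ts$adoptedDiameter
        usedTS <- TRUE
        log[[length(log) + 1]] <- list(step = step, module = "TS",
                                       stage = ts$stage, model = ts$modelId,
                                       diameter = ts$adoptedDiameter)
      }
    }
    if (is.null(mask)) {
      # a recovery failure where the volume face clips the central region
      # the cross-section would occupy is a boundary event (the tubule is
      # leaving the volume), not a correction-queue event
      nPx <- nrow(img@oob)
      cPx <- (nPx + 1) / 2
      rPx <- max(0.75 * rp$dPrime / plane@pitch, 3)
      central <- sqrt(outer((seq_len(nPx) - cPx)^2,
                            (seq_len(nPx) - cPx)^2, "+")) <= rPx
      if (mean(img@oob[central]) > 0.2) {
        status <- "terminated_boundary"
        break
      }
      flags <- rbind(flags, newFlag(id, length(pos), "no_mask_any_model", rp))
      status <- "flagged"
      break
    }
    node <- mask@centroidWorld
    prev <- pos[[length(pos)]]
    stepVec <- node - prev
    if (vecNorm(stepVec) < 1e-9) {
      flags <- rbind(flags, newFlag(id, length(pos), "stall", rp))
      status <- "flagged"; break
    }
    newForward <- if (usedRS) {
      nn <- mask@plane@normal
      if (sum(nn * forward) < 0) -nn else nn
    } else normalize(stepVec)
    # stall detection: backtracking onto old nodes, or direction reversal
    nOld <- length(pos) - config@stallLookback
    stalled <- FALSE
    if (nOld >= 1) {
      oldPts <- do.call(rbind, pos[seq_len(nOld)])
      if (min(sqrt(rowSums(sweep(oldPts, 2, node)^2))) <
          config@stallRadiusFactor * rp$S) stalled <- TRUE
    }
    if (sum(newForward * forward) < config@reversalDot) stalled <- TRUE
    pos[[length(pos) + 1]] <- node
    s <- c(s, s[length(s)] + vecNorm(stepVec))
    diamNodes <- c(diamNodes, mask@equivDiameterUm)
    modelCol <- c(modelCol, currentModelId)
    rsCol <- c(rsCol, usedRS); tsCol <- c(tsCol, usedTS)
    manCol <- c(manCol, FALSE)
    masks[[length(masks) + 1]] <- mask
    diamWindow <- if (!is.null(adoptedDiameter)) adoptedDiameter
                  else c(diamWindow, mask@equivDiameterUm)
    if (stalled) {
      flags <- rbind(flags, newFlag(id, length(pos), "stall", rp))
      status <- "flagged"; break
    }
    fr <- transportFrame(u, v, forward, newForward)
    u <- fr$u; v <- fr$v
    forward <- newForward
    if (!is.null(stopPoints) &&
        min(sqrt(rowSums(sweep(matrix(stopPoints, ncol = 3), 2, node)^2))) <=
          config@mergeToleranceUm) { status <- "complete"; break }
    # merge check starts only once the track has left its seed neighbourhood,
    # so a track seeded beside an existing centerline (e.g. at a junction)
    # can escape before being declared a duplicate
    merged <- FALSE
    if (s[length(s)] > 3 * config@mergeToleranceUm) for (ep in existingPolys) {
      if (nrow(ep) < 2) next
      if (distanceToPolyline(node, ep)$distance <= config@mergeToleranceUm) {
        status <- "terminated_merge"; merged <- TRUE; break
      }
    }
    if (merged) break
  }
  if (status == "active") status <- "complete"
  nodes <- data.frame(
    z = vapply(pos, `[`, 0, 1), y = vapply(pos, `[`, 0, 2),
    x = vapply(pos, `[`, 0, 3), s = s, diameter = diamNodes,
    model = modelCol, rotationalSearch = rsCol, troubleshoot = tsCol,
    manualCorrection = manCol, stringsAsFactors = FALSE)
  new("Track", nodes = nodes, masks = masks, seeds = seeds, status = status,
      flags = flags, interventionLog = log, id = id)
}

#' Apply a manual correction to a flagged track
#'
#' Appends the correction point(s) as manually placed nodes, clears the open
#' flag and, when `resume = TRUE` and a volume is supplied, resumes automated
#' tracking from the corrected position (forward direction recomputed from
#' the two most recent nodes).
#'
#' @param track a flagged [Track-class].
#' @param correction numeric(3) or n x 3 matrix of world um points.
#' @param resume resume automated tracking after the correction?
#' @param volume,config,models,stopPoints,existingTracks tracking context,
#'   required when `resume = TRUE`.
#' @return The corrected (and possibly resumed) [Track-class].
#' @export
applyCorrection <- function(track, correction, resume = TRUE, volume = NULL,
                            config = trackingConfig(),
                            models = list(segmentationModel("wall")),
                            stopPoints = NULL, existingTracks = list()) {
  if (track@status != "flagged")
    stop("corrections only apply to flagged tracks (status is '",
         track@status, "')")
  correction <- matrix(as.numeric(correction), ncol = 3)
  if (!is.null(volume)) {
    bounds <- worldBounds(volume)
    for (i in seq_len(nrow(correction)))
      if (!insideWorld(correction[i, ], bounds))
        stop("correction point lies outside the volume")
  }
  nodes <- track@nodes
  masks <- track@masks
  for (i in seq_len(nrow(correction))) {
    p <- correction[i, ]
    last <- as.numeric(nodes[nrow(nodes), c("z", "y", "x")])
    nodes <- rbind(nodes, data.frame(
      z = p[1], y = p[2], x = p[3],
      s = nodes$s[nrow(nodes)] + vecNorm(p - last),
      diameter = NA_real_, model = nodes$model[nrow(nodes)],
      rotationalSearch = FALSE, troubleshoot = FALSE,
      manualCorrection = TRUE, stringsAsFactors = FALSE))
    masks[[length(masks) + 1]] <- NULL
  }
  track@nodes <- nodes
  track@masks <- masks
  track@flags <- emptyFlags()
  track@interventionLog <- c(track@interventionLog,
                             list(list(module = "manual",
                                       points = correction)))
  track@status <- if (resume) "active" else "complete"
  if (resume && !is.null(volume)) {
    n <- nrow(nodes)
    resumeSeeds <- rbind(as.numeric(nodes[n - 1, c("z", "y", "x")]),
                         as.numeric(nodes[n, c("z", "y", "x")]))
    cont <- trackTubule(volume, resumeSeeds, config, models,
                        stopPoints = stopPoints,
                        existingTracks = existingTracks, id = track@id)
    cn <- cont@nodes[-(1:2), , drop = FALSE]   # the seeds duplicate our nodes
    if (nrow(cn) > 0) {
      cn$s <- cn$s - cont@nodes$s[2] + nodes$s[n]
      track@nodes <- rbind(nodes, cn)
      track@masks <- c(masks, cont@masks[-(1:2)])
    }
    track@status <- cont@status
    track@flags <- cont@flags
    if (nrow(track@flags) > 0)
      track@flags$nodeIndex <- track@flags$nodeIndex + n - 2L
    track@interventionLog <- c(track@interventionLog, cont@interventionLog)
  } else if (resume) {
    track@status <- "active"    # re-enqueued; the pipeline resumes it
  }
  track
}
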