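# Seminiferous-style wave phantom: a wide tubule whose DNA-staining pattern
# cycles through the three spermatogenic-wave classes (dark, sparse clusters,
# dense clusters) along its arc length, plus a multi-tube phantom used for
# parallelization and determinism checks.

# Rotation-minimizing frames (e1, e2) along a polyline.
rmfFrames <- function(points) {
  n <- nrow(points)
  tang <- rbind(points[2, ] - points[1, ],
                (points[pmin(3:(n + 1), n), , drop = FALSE] -
                   points[1:(n - 1), , drop = FALSE]))[1:n, , drop = FALSE]
  e1 <- matrix(0, n, 3); e2 <- matrix(0, n, 3)
  t0 <- normalize(tang[1, ])
  u <- orthoComplement(t0); v <- cross3(t0, u)
  e1[1, ] <- u; e2[1, ] <- v
  tPrev <- t0
  for (i in 2:n) {
    ti <- tang[i, ]
    nt <- vecNorm(ti)
    ti <- if (nt < 1e-12) tPrev else ti / nt
    fr <- transportFrame(u, v, tPrev, ti)
    u <- fr$u; v <- fr$v
    e1[i, ] <- u; e2[i, ] <- v
    tPrev <- ti
  }
  list(e1 = e1, e2 = e2)
}

# Default geometry/intensity of the wave phantom's staining regimes. The
# three classes are emulated as: dark = trace spermatozoa flecks only;
# sparse clusters = several thin bright cords (elongated-spermatid bundles)
# evenly spread around the epithelium, with a per-window count cycling
# through speckCounts; dense clusters = two thick bright cords at the
# epithelial rim plus two thin satellites. Decoy structures make each
# classifier threshold identifiable rather than degenerate: four faint
# cords (level between 2x and 2.5x the epithelial median) break the
# stage-1 threshold multiplier below its optimum; a sub-surface ring at an
# intensity just below the optimal second threshold welds everything into
# one giant component if that threshold dips; the satellites keep the
# dense-class cluster-dominance fraction below 0.9; the three-cord sparse
# windows push it above 0.3.
waveObjectDefaults <- function() list(
  lumenLevel = 40, epitheliumLevel = 60, ringLevel = 75,
  ringInnerFrac = 0.82, ringOuterFrac = 0.925,
  speckRadiusUm = 12, speckLevel = 220, speckCounts = c(5, 3, 7, 4, 6, 8),
  speckOffsetFrac = 0.42,
  traceRadiusUm = 7, traceLevel = 220, traceRatePerUm = 0.023,
  faintRadiusUm = 9, faintLevel = 135, faintCount = 4, faintOffsetFrac = 0.68,
  rodRadiusUm = 30, rodLevel = 220, rodStepUm = 3)

#' Generate a spermatogenic-wave phantom
#'
#' Renders a seminiferous-scale tubule (solid epithelium, small dim lumen, a
#' faint sub-surface ring) whose bright-object pattern cycles through the
#' given class runs. Ground truth records the class of every arc-length
#' interval.
#'
#' `spec@wave` must contain `pattern` (character vector of run classes from
#' dark / sparse_clusters / dense_clusters) and `extentUm` (run length, um;
#' scalar or one per run). Optional `objects` overrides
#' `waveObjectDefaults()` entries.
#'
#' @param spec a [PhantomSpec-class] with a non-empty `wave` list.
#' @return As [makeTubePhantom()]; `truth@classes` holds the planted runs.
#' @export
makeWavePhantom <- function(spec) {
  if (length(spec@wave) == 0) stop("spec has no wave pattern")
  wv <- spec@wave
  ob <- modifyList(waveObjectDefaults(),
                   if (is.null(wv$objects)) list() else wv$objects)
  pattern <- wv$pattern
  bad <- setdiff(pattern, c("dark", "sparse_clusters", "dense_clusters"))
  if (length(bad) > 0) stop("unknown wave class: ", paste(bad, collapse = ", "))
  ext <- rep_len(wv$extentUm, length(pattern))
  # base tube: banded intensities (dim lumen, mid-level epithelium, faint
  # sub-surface ring) — must be set before the tube description is built
  spec@intensity <- list(model = "bands", background = spec@intensity$background,
                         contrast = 1, lumen = ob$lumenLevel,
                         wallThicknessUm = 0, bands = list(
    list(relative = TRUE, innerFrac = -0.01, outerFrac = 0.25, level = ob$lumenLevel),
    list(relative = TRUE, innerFrac = 0.25, outerFrac = 1.0, level = ob$epitheliumLevel),
    list(relative = TRUE, innerFrac = ob$ringInnerFrac,
         outerFrac = ob$ringOuterFrac, level = ob$ringLevel)))
  hUm <- min(spec@spacing) / 4
  tube <- tubeFromSpec(spec, hUm)
  L <- max(tube$s)
  if (sum(ext) > L + 1e-6)
    stop(sprintf("class extents (%.0f um) exceed the tube length (%.0f um)",
                 sum(ext), L))
  runs <- data.frame(sStart = cumsum(c(0, ext[-length(ext)])),
                     sEnd = cumsum(ext), class = pattern,
                     stringsAsFactors = FALSE)
  rend <- renderPhantom(spec, list(tube))
  vol <- rend$volume
  # frames for placing objects in cross-section coordinates
  rs <- resamplePolyline(tube$points, 1)
  fr <- rmfFrames(rs$points)
  rad <- radiusAt(spec@radius, rs$s)
  pointAt <- function(s, rho, theta) {
    i <- pmax(1, pmin(length(rs$s), round(s) + 1))
    rs$points[i, , drop = FALSE] +
      rho * (cos(theta) * fr$e1[i, , drop = FALSE] +
               sin(theta) * fr$e2[i, , drop = FALSE])
  }
  # continuous cords are stamped as spheres every rodStepUm along arc length
  stampCord <- function(s0, s1, rhoFun, theta, radiusUm, level) {
    sSeq <- seq(s0, min(s1, max(rs$s)), by = ob$rodStepUm)
    rho <- rhoFun(sSeq)
    vol <<- stampSpheres(vol, pointAt(sSeq, rho, theta), radiusUm, level,
                         spec@spacing, spec@origin)
  }
  set.seed(spec@seed + 1)
  sparseRuns <- which(runs$class == "sparse_clusters")
  sparseN <- rep_len(ob$speckCounts, max(length(sparseRuns), 1))
  for (k in seq_len(nrow(runs))) {
    s0 <- runs$sStart[k]; s1 <- runs$sEnd[k]
    rBar <- mean(radiusAt(spec@radius, c(s0, s1)))
    phase <- stats::runif(1, 0, 2 * pi)
    if (runs$class[k] == "sparse_clusters") {
      nC <- sparseN[match(k, sparseRuns)]
      for (j in seq_len(nC))
        stampCord(s0, s1, function(s) rep(ob$speckOffsetFrac * rBar, length(s)),
                  phase + 2 * pi * (j - 1) / nC, ob$speckRadiusUm,
                  ob$speckLevel)
    } else if (runs$class[k] == "dense_clusters") {
      rhoRod <- function(s) radiusAt(spec@radius, s) - ob$rodRadiusUm - 4
      stampCord(s0, s1, rhoRod, phase, ob$rodRadiusUm, ob$rodLevel)
      stampCord(s0, s1, rhoRod, phase + pi, ob$rodRadiusUm, ob$rodLevel)
      for (j in c(0.5, 1.5))   # two thin satellites between the thick cords
        stampCord(s0, s1, function(s) rep(ob$speckOffsetFrac * rBar, length(s)),
                  phase + j * pi, ob$speckRadiusUm, ob$speckLevel)
    } else { # dark: sparse trace flecks only
      nT <- stats::rpois(1, ob$traceRatePerUm * (s1 - s0))
      if (nT > 0) {
        sT <- stats::runif(nT, s0, s1)
        rhoT <- stats::runif(nT, 0.2 * rBar, 0.6 * rBar)
        thT <- stats::runif(nT, 0, 2 * pi)
        vol <- stampSpheres(vol, pointAt(sT, rhoT, thT), ob$traceRadiusUm,
                            ob$traceLevel, spec@spacing, spec@origin)
      }
    }
    # faint decoy cords in every class, interleaved with the bright objects
    for (j in seq_len(ob$faintCount))
      stampCord(s0, s1, function(s) rep(ob$faintOffsetFrac * rBar, length(s)),
                phase + pi / 4 + 2 * pi * (j - 1) / ob$faintCount,
                ob$faintRadiusUm, ob$faintLevel)
  }
  truth <- new("PhantomTruth",
               centerline = truthCenterline(tube),
               mask = rend$unionMask,
               nuclei = data.frame(z = numeric(0), y = numeric(0),
                                   x = numeric(0), inLumen = logical(0),
                                   tubule = integer(0)),
               classes = runs, junctions = emptyJunctions()[0, 1:5],
               tubeMasks = rend$tubeMasks)
  list(volume = finishVolume(vol, spec, "dna"), truth = truth,
       nucleiVolume = NULL)
}

#' Ground-truth class at given arc lengths of a wave phantom
#'
#' @param truth a [PhantomTruth-class] with planted classes.
#' @param s arc lengths (um).
#' @return Character vector of class labels (NA outside all runs).
#' @export
truthClassAt <- function(truth, s) {
  runs <- truth@classes
  out <- rep(NA_character_, length(s))
  for (k in seq_len(nrow(runs)))
    out[s >= runs$sStart[k] & s <= runs$sEnd[k]] <- runs$class[k]
  out
}

#' Generate several independent tubes in one volume
#'
#' Used to exercise parallel, order-independent tracking: each spec renders
#' its own tube (no junctions) into a shared volume; per-tube truth masks and
#' centerlines are returned.
#'
#' @param specs list of single-tube [PhantomSpec-class] objects; volume
#'   geometry, noise and seed are taken from the first.
#' @return list(volume, truths) where `truths` is one [PhantomTruth-class]
#'   per tube.
#' @export
makeMultiTubePhantom <- function(specs) {
  base <- specs[[1]]
  hUm <- min(base@spacing) / 4
  tubes <- lapply(specs, tubeFromSpec, hUm = hUm)
  rend <- renderPhantom(base, tubes)
  truths <- lapply(seq_along(tubes), function(t)
    new("PhantomTruth", centerline = truthCenterline(tubes[[t]]),
        mask = rend$unionMask,
        nuclei = data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                            inLumen = logical(0), tubule = integer(0)),
        classes = data.frame(), junctions = emptyJunctions()[0, 1:5],
        tubeMasks = rend$tubeMasks[t]))
  list(volume = finishVolume(rend$volume, base, "carbohydrate"),
       truths = truths)
}

#' Write phantom ground truth to plain-text files
#'
#' Centerline, nuclei and class runs go to a JSON file; the truth mask to a
#' multi-page TIFF alongside it.
#'
#' @param truth a [PhantomTruth-class].
#' @param path output path prefix (creates `<path>.json` and `<path>_mask.tif`).
#' @return `path`, invisibly.
#' @export
writePhantomTruth <- function(truth, path) {
  jsonlite::write_json(list(
    centerline = truth@centerline, nuclei = truth@nuclei,
    classes = truth@classes, junctions = truth@junctions),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  m <- truth@mask
  pages <- lapply(seq_len(dim(m)[1]), function(i) m[i, , ] * 1)
  tiff::writeTIFF(pages, paste0(path, "_mask.tif"), bits.per.sample = 8)
  invisible(path)
}
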