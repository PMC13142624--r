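# Spermatogenic-wave staging: hierarchical classification of tubule
# cross-sections into dark / sparse_clusters / dense_clusters, rolling-mode
# smoothing along the tubule, wave and reversal counting, and grid-search
# calibration of the classifier thresholds.

waveClasses <- c("dark", "sparse_clusters", "dense_clusters")

#' Classify one cross-section frame
#'
#' Stage 1: pixels above threshold1 = a x median(in-mask intensity) are
#' candidate spermatozoa; if their area is less than fraction b of the
#' cross-section area the frame is dark. Stage 2: remaining frames are
#' re-thresholded at raw intensity c; if the two largest 8-connected
#' components hold less than fraction d of the bright area the frame is
#' sparse_clusters, else dense_clusters.
#'
#' @param frame a [PlaneImage-class] or numeric matrix.
#' @param mask logical matrix covering the tubule cross-section.
#' @param params a [WaveClassifierParams-class].
#' @return One of "dark", "sparse_clusters", "dense_clusters".
#' @export
classifyFrame <- function(frame, mask, params) {
  px <- if (is(frame, "PlaneImage")) frame@pixels else frame
  if (!any(mask)) stop("empty cross-section mask")
  vals <- px[mask]
  thr1 <- params@a * stats::median(vals)
  b1Frac <- mean(vals > thr1)
  if (b1Frac < params@b) return("dark")
  bright <- px > params@c & mask
  tot <- sum(bright)
  if (tot == 0) return("sparse_clusters")
  lab <- labelComponents(bright, full = TRUE)
  areas <- sort(tabulate(lab[lab > 0]), decreasing = TRUE)
  f2 <- sum(areas[seq_len(min(2, length(areas)))]) / tot
  if (f2 < params@d) "sparse_clusters" else "dense_clusters"
}

#' Classify every frame of a straightened stack
#'
#' @param stack a [StraightenedStack-class].
#' @param params a [WaveClassifierParams-class].
#' @param maskRadiusUm cross-section disk radius used as the mask (um);
#'   or `masks`, an explicit list of logical matrices per frame.
#' @param masks optional explicit masks.
#' @return A [StageSequence-class] with raw labels (smoothed = NA).
#' @export
classifyStack <- function(stack, params, maskRadiusUm = NULL, masks = NULL) {
  d <- dim(stack@frames)
  if (is.null(masks)) {
    if (is.null(maskRadiusUm)) stop("give maskRadiusUm or masks")
    pitch <- stack@planes[[1]]@pitch
    c0 <- (d[1] + 1) / 2
    rr <- sqrt(outer((seq_len(d[1]) - c0)^2, (seq_len(d[2]) - c0)^2, "+"))
    diskMask <- rr * pitch <= maskRadiusUm
    masks <- rep(list(diskMask), d[3])
  }
  raw <- vapply(seq_len(d[3]), function(k)
    classifyFrame(stack@frames[, , k], masks[[k]], params), "")
  new("StageSequence",
      frames = data.frame(s = stack@arcLengths, raw = raw,
                          smoothed = NA_character_, stringsAsFactors = FALSE),
      waves = data.frame(startUm = numeric(0), endUm = numeric(0),
                         direction = character(0)),
      reversals = 0L)
}

#' Smooth class labels with a rolling modal window
#'
#' The smoothed label at arc length s is the modal raw label within
#' [s - w/2, s + w/2]; ties resolve to the previous smoothed label.
#'
#' @param seq a [StageSequence-class] (frames ordered by arc length).
#' @param windowUm window width w (um), default from the classifier
#'   convention (2 mm).
#' @return The [StageSequence-class] with `smoothed` filled in.
#' @export
smoothLabels <- function(seq, windowUm = 2000) {
  fr <- seq@frames
  n <- nrow(fr)
  sm <- character(n)
  prev <- fr$raw[1]
  for (i in seq_len(n)) {
    sel <- fr$s >= fr$s[i] - windowUm / 2 & fr$s <= fr$s[i] + windowUm / 2
    tab <- table(fr$raw[sel])
    best <- names(tab)[tab == max(tab)]
    sm[i] <- if (length(best) == 1) best
             else if (prev %in% best) prev else best[1]
    prev <- sm[i]
  }
  seq@frames$smoothed <- sm
  seq
}

# Direction of a transition between two distinct classes in the cyclic order
# dark -> sparse_clusters -> dense_clusters -> dark: +1 forward, -1 reverse.
transitionDirection <- function(from, to) {
  d <- (match(to, waveClasses) - match(from, waveClasses)) %% 3
  if (d == 1) 1L else -1L
}

#' Count complete waves and reversals along a staged tubule
#'
#' Consecutive duplicate labels are collapsed to runs; a complete wave is
#' three consecutive runs covering all three classes with both transitions
#' in the same cyclic direction; a reversal is a change of direction between
#' adjacent transitions.
#'
#' @param seq a [StageSequence-class] with smoothed labels (raw labels are
#'   used if smoothing has not been applied).
#' @return The [StageSequence-class] with `waves` and `reversals` filled in.
#' @export
countWaves <- function(seq) {
  fr <- seq@frames
  lab <- if (all(is.na(fr$smoothed))) fr$raw else fr$smoothed
  keep <- c(TRUE, lab[-1] != lab[-length(lab)])
  runLab <- lab[keep]
  runStart <- fr$s[keep]
  runEnd <- c(runStart[-1], max(fr$s))
  nR <- length(runLab)
  waves <- data.frame(startUm = numeric(0), endUm = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
  if (nR >= 2) {
    dirs <- vapply(seq_len(nR - 1), function(j)
      transitionDirection(runLab[j], runLab[j + 1]), 1L)
    i <- 1
    while (i + 2 <= nR) {
      triple <- runLab[i:(i + 2)]
      if (length(unique(triple)) == 3 && dirs[i] == dirs[i + 1]) {
        waves <- rbind(waves, data.frame(
          startUm = runStart[i], endUm = runEnd[i + 2],
          direction = if (dirs[i] == 1) "forward" else "reverse",
          stringsAsFactors = FALSE))
        i <- i + 3
      } else i <- i + 1
    }
    reversals <- sum(dirs[-1] != dirs[-length(dirs)])
  } else reversals <- 0L
  seq@waves <- waves
  seq@reversals <- as.integer(reversals)
  seq
}

#' Calibrate the wave classifier by exhaustive grid search
#'
#' Every (a, b, c, d) combination of the supplied grids is evaluated against
#' the labelled frames; the combination with the highest macro-F1 wins, with
#' ties broken toward smaller a, then smaller c, then smaller b, then
#' smaller d. Per-frame statistics are precomputed so the grid sweep is
#' cheap: the stage-1 bright fraction depends only on a, and the stage-2
#' cluster-dominance fraction only on c.
#'
#' @param frames list of numeric matrices (or [PlaneImage-class]).
#' @param masks list of logical masks (or a single mask recycled).
#' @param labels character vector of true classes per frame.
#' @param grids list(a=, b=, c=, d=) of candidate values.
#' @return list(params = [WaveClassifierParams-class], macroF1, table =
#'   data.frame of every combination and its score).
#' @export
calibrateParams <- function(frames, masks, labels, grids) {
  if (any(vapply(grids[c("a", "b", "c", "d")], length, 0L) == 0))
    stop("empty parameter grid")
  if (length(unique(labels)) < 2)
    stop("calibration needs at least 2 classes represented")
  nF <- length(frames)
  if (!is.list(masks)) masks <- rep(list(masks), nF)
  if (length(masks) == 1 && nF > 1) masks <- rep(masks, nF)
  mats <- lapply(frames, function(f) if (is(f, "PlaneImage")) f@pixels else f)
  # per-frame precomputation
  b1Frac <- matrix(0, nF, length(grids$a))
  f2Frac <- matrix(0, nF, length(grids$c))
  for (i in seq_len(nF)) {
    vals <- mats[[i]][masks[[i]]]
    med <- stats::median(vals)
    for (ai in seq_along(grids$a))
      b1Frac[i, ai] <- mean(vals > grids$a[ai] * med)
    for (ci in seq_along(grids$c)) {
      bright <- mats[[i]] > grids$c[ci] & masks[[i]]
      tot <- sum(bright)
      if (tot == 0) { f2Frac[i, ci] <- 0; next }
      lab <- labelComponents(bright, full = TRUE)
      areas <- sort(tabulate(lab[lab > 0]), decreasing = TRUE)
      f2Frac[i, ci] <- sum(areas[seq_len(min(2, length(areas)))]) / tot
    }
  }
  classesPresent <- intersect(waveClasses, unique(labels))
  macroF1 <- function(pred) {
    f1s <- vapply(classesPresent, function(cl) {
      tp <- sum(pred == cl & labels == cl)
      fp <- sum(pred == cl & labels != cl)
      fn <- sum(pred != cl & labels == cl)
      if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    }, 0)
    mean(f1s)
  }
  tab <- NULL
  best <- NULL
  for (ai in seq_along(grids$a)) for (bi in seq_along(grids$b))
    for (ci in seq_along(grids$c)) for (di in seq_along(grids$d)) {
      dark <- b1Frac[, ai] < grids$b[bi]
      pred <- ifelse(dark, "dark",
                     ifelse(f2Frac[, ci] < grids$d[di],
                            "sparse_clusters", "dense_clusters"))
      f1 <- macroF1(pred)
      tab <- rbind(tab, data.frame(a = grids$a[ai], b = grids$b[bi],
                                   c = grids$c[ci], d = grids$d[di],
                                   macroF1 = f1))
      cand <- c(grids$a[ai], grids$c[ci], grids$b[bi], grids$d[di])
      better <- is.null(best) || f1 > best$f1 + 1e-12 ||
        (abs(f1 - best$f1) <= 1e-12 &&
           isTRUE(all(cand == best$cand)[1]) == FALSE &&
           {
             cmp <- sign(cand - best$cand)
             nz <- which(cmp != 0)
             length(nz) > 0 && cmp[nz[1]] < 0
           })
      if (better)
        best <- list(f1 = f1, cand = cand,
                     params = waveClassifierParams(
                       a = grids$a[ai], b = grids$b[bi],
                       c = grids$c[ci], d = grids$d[di]))
    }
  list(params = best$params, macroF1 = best$f1, table = tab)
}
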