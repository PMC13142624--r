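# Track merging and branch-point identification. Overlaps between
# reconstructions are found by Euclidean distance between centerlines; the
# shorter overlapping portion is truncated and a junction recorded. Branch
# points are junctions where 3 or more segments meet; a junction formed
# where a segment rejoins a tubule it already joins is a reconnection, not
# an additional branch point.

resampleTrackPolyline <- function(track, h) {
  pts <- as.matrix(track@nodes[, c("z", "y", "x")])
  if (nrow(pts) < 2) return(list(points = pts, s = track@nodes$s))
  resamplePolyline(pts, h)
}

addJunction <- function(jn, p, degree, kind, a, b, tol) {
  if (nrow(jn) > 0) {
    same <- jn$trackA == a & jn$trackB == b &
      sqrt((jn$z - p[1])^2 + (jn$y - p[2])^2 + (jn$x - p[3])^2) <= 2 * tol
    if (any(same)) return(jn)
  }
  rbind(jn, data.frame(z = p[1], y = p[2], x = p[3], degree = degree,
                       kind = kind, trackA = a, trackB = b,
                       stringsAsFactors = FALSE))
}

truncateTrack <- function(track, keepIdx) {
  track@nodes <- track@nodes[keepIdx, , drop = FALSE]
  track@masks <- track@masks[keepIdx]
  track@nodes$s <- track@nodes$s - track@nodes$s[1]
  rownames(track@nodes) <- NULL
  track
}

reverseTrack <- function(track) {
  n <- nrow(track@nodes)
  track@nodes <- track@nodes[n:1, , drop = FALSE]
  track@nodes$s <- max(track@nodes$s) - track@nodes$s
  track@masks <- track@masks[n:1]
  rownames(track@nodes) <- NULL
  track
}

spliceTracks <- function(a, b) {
  # append b's nodes to a's end (end-to-end continuation)
  bn <- b@nodes
  an <- a@nodes
  gap <- vecNorm(as.numeric(bn[1, c("z", "y", "x")]) -
                   as.numeric(an[nrow(an), c("z", "y", "x")]))
  bn$s <- bn$s - bn$s[1] + an$s[nrow(an)] + max(gap, 1e-6)
  a@nodes <- rbind(an, bn)
  a@masks <- c(a@masks, b@masks)
  a@interventionLog <- c(a@interventionLog, b@interventionLog)
  a
}

# Distance of each node of `tr` to the accepted track polyline.
nodeDistances <- function(tr, polyA) {
  distanceToPolyline(as.matrix(tr@nodes[, c("z", "y", "x")]),
                     polyA$points, s = polyA$s)
}

#' Merge overlapping tracks into a tubule network
#'
#' Tracks are compared pairwise (longest first). Where a shorter track's
#' centerline runs within `toleranceUm` of an already accepted track, the
#' overlapping portion of the shorter track is truncated: a fully covered
#' track is absorbed; an end-to-end continuation is spliced into a single
#' centerline; a lateral arrival creates a junction. The first junction
#' between a pair of tracks is a branch; any further junction between the
#' same pair (a segment rejoining the tubule it already joins) is a
#' reconnection. The operation is idempotent on a merged network.
#'
#' @param tracks list of [Track-class], or a [TubuleNetwork-class].
#' @param toleranceUm centerline distance defining an overlap (um).
#' @return A [TubuleNetwork-class].
#' @export
mergeTracks <- function(tracks, toleranceUm = 15) {
  if (is(tracks, "TubuleNetwork")) tracks <- tracks@tracks
  ord <- order(vapply(tracks, trackLength, 0), decreasing = TRUE)
  tracks <- tracks[ord]
  accepted <- list()
  jn <- emptyJunctions()
  for (tr in tracks) {
    absorbed <- FALSE
    if (nrow(tr@nodes) >= 2) for (ai in seq_along(accepted)) {
      A <- accepted[[ai]]
      if (nrow(A@nodes) < 2) next
      polyA <- resampleTrackPolyline(A, toleranceUm / 2)
      jKind <- function() if (any(jn$trackA == A@id & jn$trackB == tr@id))
        "reconnection" else "branch"
      # -- head overlap ---------------------------------------------------
      nd <- nodeDistances(tr, polyA)
      ov <- nd$distance <= toleranceUm
      if (!any(ov)) next
      if (all(ov)) { absorbed <- TRUE; break }
      if (ov[1]) {
        keepFrom <- which(!ov)[1]
        jIdx <- keepFrom - 1
        sA <- nd$s[jIdx]
        jp <- as.numeric(tr@nodes[jIdx, c("z", "y", "x")])
        if (sA >= max(polyA$s) - toleranceUm) {
          # continues past A's far end: splice into one centerline
          accepted[[ai]] <- spliceTracks(A, truncateTrack(
            tr, keepFrom:nrow(tr@nodes)))
          absorbed <- TRUE; break
        } else if (sA <= toleranceUm) {
          accepted[[ai]] <- spliceTracks(
            reverseTrack(truncateTrack(tr, keepFrom:nrow(tr@nodes))), A)
          absorbed <- TRUE; break
        } else {
          jn <- addJunction(jn, jp, 3L, jKind(), A@id, tr@id, toleranceUm)
          tr <- truncateTrack(tr, jIdx:nrow(tr@nodes))
        }
      }
      # -- tail overlap ---------------------------------------------------
      nd <- nodeDistances(tr, polyA)
      ov <- nd$distance <= toleranceUm
      nB <- nrow(tr@nodes)
      if (ov[nB] && !all(ov)) {
        keepTo <- max(which(!ov))
        jIdx <- keepTo + 1
        sA <- nd$s[jIdx]
        jp <- as.numeric(tr@nodes[jIdx, c("z", "y", "x")])
        if (sA >= max(polyA$s) - toleranceUm) {
          accepted[[ai]] <- spliceTracks(A, reverseTrack(
            truncateTrack(tr, 1:keepTo)))
          absorbed <- TRUE; break
        } else if (sA <= toleranceUm) {
          accepted[[ai]] <- spliceTracks(truncateTrack(tr, 1:jIdx), A)
          absorbed <- TRUE; break
        } else {
          jn <- addJunction(jn, jp, 3L, jKind(), A@id, tr@id, toleranceUm)
          tr <- truncateTrack(tr, 1:jIdx)
        }
      } else if (!ov[1] && !ov[nB] && any(ov)) {
        # interior tangential contact: record the closest approach
        k <- which.min(nd$distance)
        jp <- as.numeric(tr@nodes[k, c("z", "y", "x")])
        jn <- addJunction(jn, jp, 3L, jKind(), A@id, tr@id, toleranceUm)
      }
    }
    if (!absorbed) accepted[[length(accepted) + 1]] <- tr
  }
  new("TubuleNetwork", tracks = accepted, junctions = jn)
}

#' Identify branch points of a merged network
#'
#' @param network a [TubuleNetwork-class] from [mergeTracks()].
#' @return The junction data.frame restricted to branch points (3 or more
#'   incident segments); reconnection events are excluded by definition.
#' @export
findBranchPoints <- function(network) {
  jn <- junctions(network)
  jn[jn$kind == "branch" & jn$degree >= 3, , drop = FALSE]
}

#' Build a Track from explicit centerline points
#'
#' Wraps an externally supplied centerline (a manual annotation, a phantom
#' ground truth, an imported reconstruction) as a [Track-class] so it can
#' enter [mergeTracks()], [morphometricProfiles()] or [straightenTubule()].
#'
#' @param points n x 3 matrix or data.frame of world (z, y, x) um.
#' @param id track identifier.
#' @param diameter optional per-point (or scalar) diameter in um.
#' @param stepUm resampling step; NULL keeps the points as given.
#' @return A [Track-class] with status "complete" and no masks.
#' @export
trackFromPoints <- function(points, id = "manual", diameter = NA_real_,
                            stepUm = NULL) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("z", "y", "x")])
  if (!is.null(stepUm)) points <- resamplePolyline(points, stepUm)$points
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
  nodes <- data.frame(
    z = points[, 1], y = points[, 2], x = points[, 3],
    s = c(0, cumsum(seg)), diameter = rep_len(diameter, nrow(points)),
    model = "external", rotationalSearch = FALSE, troubleshoot = FALSE,
    manualCorrection = FALSE, stringsAsFactors = FALSE)
  new("Track", nodes = nodes, masks = rep(list(NULL), nrow(points)),
      seeds = points[c(1, min(2, nrow(points))), , drop = FALSE],
      status = "complete", flags = emptyFlags(), interventionLog = list(),
      id = id)
}
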