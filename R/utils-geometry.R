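# Internal vector geometry helpers. All world coordinates are (z, y, x) in
# micrometres; voxel indices are 1-based in R arrays of dim (nz, ny, nx).

vecNorm <- function(v) sqrt(sum(v * v))

normalize <- function(v) {
  n <- vecNorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rodrigues rotation of vector v about unit axis k by angle theta (radians).
rotateAbout <- function(v, k, theta) {
  ct <- cos(theta); st <- sin(theta)
  v * ct + cross3(k, v) * st + k * sum(k * v) * (1 - ct)
}

# Any unit vector orthogonal to n.
orthoComplement <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  normalize(cross3(n, ref))
}

# Rotation-minimizing transport of an in-plane frame (u, v) from normal nOld
# onto normal nNew: rotate about nOld x nNew by the angle between the normals,
# then re-orthogonalize against nNew to absorb numerical drift.
transportFrame <- function(u, v, nOld, nNew) {
  nOld <- normalize(nOld); nNew <- normalize(nNew)
  ax <- cross3(nOld, nNew)
  s <- vecNorm(ax)
  if (s < 1e-12) {
    if (sum(nOld * nNew) < 0) { u <- -u } # 180 degree flip: keep right-handedness
  } else {
    ax <- ax / s
    theta <- atan2(s, sum(nOld * nNew))
    u <- rotateAbout(u, ax, theta)
  }
  u <- normalize(u - sum(u * nNew) * nNew)
  v <- normalize(cross3(nNew, u))
  list(u = u, v = v)
}

# Uniform arc-length resampling of a polyline (n x 3 matrix) at step h (um).
# Returns list(points, s) with s the arc length of each resampled point.
resamplePolyline <- function(pts, h) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2) stop("polyline needs at least 2 points")
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  keep <- c(TRUE, seg > 1e-12)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 2) stop("polyline is degenerate (all points coincide)")
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  cs <- c(0, cumsum(seg))
  L <- cs[length(cs)]
  sOut <- seq(0, L, by = h)
  if (sOut[length(sOut)] < L - 1e-9) sOut <- c(sOut, L)
  out <- cbind(
    approx(cs, pts[, 1], xout = sOut)$y,
    approx(cs, pts[, 2], xout = sOut)$y,
    approx(cs, pts[, 3], xout = sOut)$y)
  list(points = out, s = sOut)
}

polylineLength <- function(pts) {
  pts <- as.matrix(pts)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

# Minimum distance from each query point (m x 3) to a polyline (n x 3),
# together with the arc length of the closest point. Vectorized over segments.
distanceToPolyline <- function(query, pts, s = NULL) {
  query <- matrix(as.numeric(query), ncol = 3)
  pts <- as.matrix(pts)
  if (is.null(s)) {
    seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
    s <- c(0, cumsum(seg))
  }
  m <- nrow(query)
  best <- rep(Inf, m); bestS <- rep(NA_real_, m)
  a <- pts[-nrow(pts), , drop = FALSE]
  b <- pts[-1, , drop = FALSE]
  d <- b - a
  len2 <- rowSums(d * d)
  for (i in seq_len(nrow(a))) {
    if (len2[i] < 1e-24) next
    w <- sweep(query, 2, a[i, ])
    t <- pmin(pmax((w %*% d[i, ]) / len2[i], 0), 1)
    px <- a[i, 1] + t * d[i, 1]; py <- a[i, 2] + t * d[i, 2]; pz <- a[i, 3] + t * d[i, 3]
    dist2 <- (query[, 1] - px)^2 + (query[, 2] - py)^2 + (query[, 3] - pz)^2
    upd <- dist2 < best
    if (any(upd)) {
      best[upd] <- dist2[upd]
      bestS[upd] <- s[i] + t[upd] * (s[i + 1] - s[i])
    }
  }
  list(distance = sqrt(best), s = bestS)
}

# Connected-component labelling of a logical 2D matrix or 3D array with full
# (8- in 2D, 26- in 3D) or face (4-/6-) connectivity. Returns an integer array
# of the same shape; 0 = background, components numbered from 1.
labelComponents <- function(x, full = TRUE) {
  dm <- dim(x)
  is2d <- length(dm) == 2
  if (is2d) { x <- array(x, dim = c(dm, 1)); dm <- dim(x) }
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (!full) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (dm[3] == 1) offs <- offs[offs[, 3] == 0, , drop = FALSE]
  lab <- array(0L, dim = dm)
  fg <- which(x)
  if (length(fg) == 0) {
    if (is2d) return(matrix(0L, nrow = dm[1], ncol = dm[2]))
    return(lab)
  }
  nz <- dm[1]; nzy <- dm[1] * dm[2]
  nextLab <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    nextLab <- nextLab + 1L
    lab[seed] <- nextLab
    frontier <- seed
    while (length(frontier) > 0) {
      i0 <- ((frontier - 1) %% nz) + 1
      j0 <- (((frontier - 1) %/% nz) %% dm[2]) + 1
      k0 <- ((frontier - 1) %/% nzy) + 1
      ii <- rep(i0, each = nrow(offs)) + offs[, 1]
      jj <- rep(j0, each = nrow(offs)) + offs[, 2]
      kk <- rep(k0, each = nrow(offs)) + offs[, 3]
      ok <- ii >= 1 & ii <= dm[1] & jj >= 1 & jj <= dm[2] & kk >= 1 & kk <= dm[3]
      lin <- unique(ii[ok] + (jj[ok] - 1) * nz + (kk[ok] - 1) * nzy)
      lin <- lin[x[lin] & lab[lin] == 0L]
      lab[lin] <- nextLab
      frontier <- lin
    }
  }
  if (is2d) lab <- array(lab, dim = dm[1:2])
  lab
}

# Deterministic k-means (farthest-point initialization, Lloyd iterations) used
# to split merged nuclei blobs; stats::kmeans with explicit centers would also
# be deterministic but needs a guard against empty clusters.
splitPointsKmeans <- function(coords, k, iters = 25) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k <= 1 || n <= k) return(rep(1L, n))
  ctr <- matrix(0, k, ncol(coords))
  ctr[1, ] <- coords[which.max(rowSums(sweep(coords, 2, colMeans(coords))^2)), ]
  d2 <- rowSums(sweep(coords, 2, ctr[1, ])^2)
  for (j in 2:k) {
    ctr[j, ] <- coords[which.max(d2), ]
    d2 <- pmin(d2, rowSums(sweep(coords, 2, ctr[j, ])^2))
  }
  assign <- rep(1L, n)
  for (it in seq_len(iters)) {
    dd <- sapply(seq_len(k), function(j) rowSums(sweep(coords, 2, ctr[j, ])^2))
    newAssign <- max.col(-dd, ties.method = "first")
    if (all(newAssign == assign) && it > 1) break
    assign <- newAssign
    for (j in seq_len(k)) {
      sel <- assign == j
      if (any(sel)) ctr[j, ] <- colMeans(coords[sel, , drop = FALSE])
    }
  }
  assign
}
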