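# Voxel reconstruction, straightening, longitudinal views, region labels.

test_that("a constant-radius track reconstructs the analytic cylinder volume", {
  tr <- straightTrackFixture()
  ph <- straightFixture()
  rec <- interpolateCrossSections(tr, ph$volume)
  nd <- trackNodes(tr)
  L <- max(nd$s) - nd$s[3]   # mask-bearing portion
  vol <- sum(maskArray(rec)) * prod(spacing(ph$volume))
  expect_lt(abs(vol - pi * 20^2 * L) / (pi * 20^2 * L), 0.1)
})

test_that("reconstruction requires at least two mask-bearing nodes", {
  tr <- straightTrackFixture()
  ph <- straightFixture()
  short <- tr
  short@nodes <- tr@nodes[1:3, ]
  short@masks <- tr@masks[1:3]   # only node 3 carries a mask
  expect_error(interpolateCrossSections(short, ph$volume), "at least 2")
})

test_that("reconstruction foreground stays local to the tracked nodes", {
  tr <- straightTrackFixture()
  ph <- straightFixture()
  rec <- interpolateCrossSections(tr, ph$volume)
  nd <- trackNodes(tr)
  # crop bounds stay within the node bounding box dilated by the plane size
  D <- 2.5 * max(nd$diameter, na.rm = TRUE)
  lo <- rec@offset
  hi <- rec@offset + dim(maskArray(rec)) - 1
  expect_gte(lo[1], min(nd$z) - D)
  expect_lte(hi[1], max(nd$z) + D)
  expect_lte(hi[3], max(nd$x) + D)
})

test_that("reconstruction against phantom truth reaches the expected overlap", {
  tr <- straightTrackFixture()
  ph <- straightFixture()
  rec <- interpolateCrossSections(tr, ph$volume)
  mm <- maskMetrics(rec, maskArray(ph$truth))
  expect_gte(mm$iou, 0.85)
  expect_gte(mm$f1, 0.9)
  # metric consistency: F1 = 2PR/(P+R)
  expect_equal(mm$f1, 2 * mm$precision * mm$recall / (mm$precision + mm$recall))
})

test_that("straightening a straight tube reproduces direct orthogonal slices", {
  ph <- straightFixture()
  tr <- straightTrackFixture()
  st <- straightenTubule(ph$volume, tr, intervalUm = 10)
  nd <- trackNodes(tr)
  expect_identical(dim(st@frames)[3],
                   as.integer(floor((max(nd$s) - min(nd$s)) / 10) + 1))
  k <- 40
  pl <- st@planes[[k]]
  direct <- samplePlane(ph$volume, pl)
  expect_identical(st@frames[, , k], direct@pixels)
  expect_lt(acos(abs(sum(pl@normal * c(0, 0, 1)))) * 180 / pi, 3)
  # interval = track length gives the two end frames
  L <- max(nd$s) - min(nd$s)
  st2 <- straightenTubule(ph$volume, tr, intervalUm = L - 1e-6)
  expect_identical(dim(st2@frames)[3], 2L)
  expect_error(straightenTubule(ph$volume, tr, intervalUm = L + 10),
               "exceeds")
  expect_error(straightenTubule(ph$volume, tr, intervalUm = 0), "> 0")
})

test_that("cross-sections of a straightened bend keep a constant diameter", {
  ph <- smoothBendFixture()
  tr <- trackFromPoints(ph$truth@centerline, id = "arc", stepUm = 6)
  st <- straightenTubule(ph$volume, tr, intervalUm = 15, sideUm = 46)
  m <- segmentationModel("wall", diameterPriorUm = 30)
  ds <- c()
  for (k in seq(3, dim(st@frames)[3] - 2, by = 3)) {
    img <- new("PlaneImage", pixels = st@frames[, , k],
               oob = matrix(FALSE, dim(st@frames)[1], dim(st@frames)[2]),
               plane = st@planes[[k]])
    msk <- selectCenterMask(segmentPlane(img, m), img)
    if (!is.null(msk)) ds <- c(ds, msk@equivDiameterUm)
  }
  expect_gte(length(ds), 10)
  expect_lt(stats::sd(ds) / mean(ds), 0.1)
  expect_equal(mean(ds), 30, tolerance = 0.1)
})

test_that("longitudinal views cut the stack along its centre row", {
  ph <- straightFixture()
  tr <- straightTrackFixture()
  st <- straightenTubule(ph$volume, tr, intervalUm = 10)
  lv <- longitudinalView(st)
  expect_identical(ncol(lv), dim(st@frames)[3])
  expect_identical(nrow(lv), dim(st@frames)[1])
  # wall-bright tube: two bright lines about one diameter apart
  colProfile <- rowMeans(lv)
  c0 <- round((nrow(lv) + 1) / 2)
  bright <- which(colProfile > 0.6 * max(colProfile))
  expect_gt(max(bright) - min(bright), 30)
  expect_lt(max(bright) - min(bright), 50)
  # single-frame stack gives a single-column image
  one <- st
  one@frames <- st@frames[, , 1, drop = FALSE]
  expect_identical(ncol(longitudinalView(one)), 1L)
})

test_that("region labels and transitions follow a planted atlas boundary", {
  ph <- straightFixture()
  tr <- straightTrackFixture()
  atlas <- array(1L, dim = dim(intensities(ph$volume)))
  atlas[, , 522:1043] <- 2L   # boundary at x = 521 um
  av <- voxelGrid(atlas, spacing = spacing(ph$volume))
  res <- assignRegions(tr, av, labelMap = c("1" = "cortex", "2" = "OSOM"))
  expect_identical(unique(res$labels), c("cortex", "OSOM"))
  expect_identical(nrow(res$transitions), 1L)
  nd <- trackNodes(tr)
  xAt <- approx(nd$s, nd$x, xout = res$transitions$sUm)$y
  expect_lt(abs(xAt - 521), 10)   # within one node spacing of the boundary
  # an all-zero atlas gives only "unassigned" and no transitions
  blank <- voxelGrid(array(0L, dim = dim(atlas)), spacing = spacing(ph$volume))
  res0 <- assignRegions(tr, blank)
  expect_identical(unique(res0$labels), "unassigned")
  expect_identical(nrow(res0$transitions), 0L)
})

test_that("mask metrics match closed forms on constructed masks", {
  a <- array(FALSE, c(4, 4, 4)); a[1:2, , ] <- TRUE
  expect_equal(maskMetrics(a, a), list(iou = 1, f1 = 1, precision = 1,
                                       recall = 1))
  b <- array(FALSE, c(4, 4, 4)); b[3:4, , ] <- TRUE
  mm <- maskMetrics(a, b)
  expect_identical(mm$iou, 0)
  expect_identical(mm$f1, 0)
  # equal-size masks overlapping on half their voxels
  c1 <- array(FALSE, c(4, 4, 4)); c1[1:2, , ] <- TRUE
  c2 <- array(FALSE, c(4, 4, 4)); c2[2:3, , ] <- TRUE
  mm2 <- maskMetrics(c1, c2)
  expect_equal(mm2$iou, 1 / 3)
  expect_equal(mm2$f1, 1 / 2)
  expect_error(maskMetrics(array(FALSE, c(2, 2, 2)), array(FALSE, c(2, 2, 2))),
               "empty")
})
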