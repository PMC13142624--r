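# 2D segmentation backends, centre-mask selection, ellipse geometry, and
# SSIM-based frame selection.

diskImage <- function(n = 80, r = 15, level = 200, bg = 20,
                      centers = list(c(0, 0)), pitch = 1) {
  px <- matrix(bg, n, n)
  c0 <- (n + 1) / 2
  for (ct in centers) {
    rr <- sqrt(outer((seq_len(n) - c0 - ct[1])^2,
                     (seq_len(n) - c0 - ct[2])^2, "+"))
    px[rr <= r] <- level
  }
  plane <- orientedPlane(center = c(0, 0, 0), normal = c(1, 0, 0),
                         side = n * pitch, pitch = pitch)
  new("PlaneImage", pixels = px, oob = matrix(FALSE, n, n), plane = plane)
}

test_that("the threshold backend finds bright disks and declares blanks", {
  m <- segmentationModel("wall", diameterPriorUm = 30)
  one <- segmentPlane(diskImage(), m)
  expect_true(one@success)
  expect_identical(max(one@labels), 1L)
  blank <- diskImage(level = 20)   # constant image
  out <- segmentPlane(blank, m)
  expect_false(out@success)
  expect_identical(max(out@labels), 0L)
  two <- segmentPlane(diskImage(centers = list(c(-18, -18), c(18, 18))), m)
  expect_identical(max(two@labels), 2L)
})

test_that("objects far from the diameter prior are not segmented", {
  img <- diskImage(r = 8)          # a 16 um object
  expect_null(selectCenterMask(segmentPlane(
    img, segmentationModel("wall", diameterPriorUm = 40)), img))
  expect_false(is.null(selectCenterMask(segmentPlane(
    img, segmentationModel("wall", diameterPriorUm = 20)), img)))
})

test_that("centre-mask selection returns the centre object or nothing", {
  img <- diskImage(centers = list(c(-25, -25), c(0, 0)))
  m <- segmentationModel("wall", diameterPriorUm = 30)
  out <- segmentPlane(img, m)
  msk <- selectCenterMask(out, img)
  expect_false(is.null(msk))
  # equivalent-diameter formula d = 2 sqrt(A/pi)
  expect_equal(msk@equivDiameterUm, 2 * sqrt(msk@areaUm2 / pi))
  expect_equal(msk@equivDiameterUm, 30, tolerance = 0.05)
  # centre on background
  offimg <- diskImage(centers = list(c(-25, -25)))
  expect_null(selectCenterMask(segmentPlane(offimg, m), offimg))
  # selection is independent of label numbering: relabel by swapping
  out2 <- out
  out2@labels <- ifelse(out@labels == 1L, 2L,
                        ifelse(out@labels == 2L, 1L, 0L))
  dim(out2@labels) <- dim(out@labels)
  msk2 <- selectCenterMask(out2, img)
  expect_identical(msk@mask, msk2@mask)
})

test_that("the second-moment ellipse recovers axes, angle and eccentricity", {
  n <- 201
  c0 <- (n + 1) / 2
  mk <- function(a, b, phi) {
    xx <- outer(rep(1, n), seq_len(n) - c0)   # u along columns
    yy <- outer(seq_len(n) - c0, rep(1, n))   # v along rows
    u <- xx * cos(phi) + yy * sin(phi)
    v <- -xx * sin(phi) + yy * cos(phi)
    (u / a)^2 + (v / b)^2 <= 1
  }
  disk <- fitEllipse(mk(40, 40, 0))
  expect_lte(disk$eccentricity, 0.05)
  ell <- fitEllipse(mk(80, 40, 0))
  expect_equal(ell$eccentricity, sqrt(1 - 0.25), tolerance = 0.02)
  expect_equal(ell$major / ell$minor, 2, tolerance = 0.03)
  rot <- fitEllipse(mk(80, 40, pi / 4))
  expect_lt(abs(abs(rot$phi) - pi / 4), 2 * pi / 180)
  expect_error(fitEllipse(matrix(c(rep(FALSE, 20), rep(TRUE, 5)), 5, 5)),
               "degenerate")
})

test_that("equivalent diameter is invariant to in-plane rotation", {
  m <- segmentationModel("wall", diameterPriorUm = 30)
  base <- selectCenterMask(segmentPlane(diskImage(r = 14), m),
                           diskImage(r = 14))
  # rotating a disk is a no-op; use an anisotropic object instead
  n <- 101; c0 <- 51
  mkimg <- function(phi) {
    xx <- outer(rep(1, n), seq_len(n) - c0)
    yy <- outer(seq_len(n) - c0, rep(1, n))
    u <- xx * cos(phi) + yy * sin(phi)
    v <- -xx * sin(phi) + yy * cos(phi)
    px <- matrix(20, n, n)
    px[(u / 18)^2 + (v / 12)^2 <= 1] <- 200
    new("PlaneImage", pixels = px, oob = matrix(FALSE, n, n),
        plane = orientedPlane(c(0, 0, 0), c(1, 0, 0), n, 1))
  }
  ds <- vapply(c(0, 0.4, 0.9, 1.3), function(phi) {
    img <- mkimg(phi)
    selectCenterMask(segmentPlane(img, m), img)@equivDiameterUm
  }, 0)
  expect_lt(diff(range(ds)) / mean(ds), 0.02)
})

test_that("highly elongated objects are rejected by the shape prior", {
  n <- 101; c0 <- 51
  px <- matrix(20, n, n)
  xx <- outer(rep(1, n), seq_len(n) - c0)
  yy <- outer(seq_len(n) - c0, rep(1, n))
  px[(xx / 45)^2 + (yy / 6)^2 <= 1] <- 200   # aspect 7.5, e = 0.993
  img <- new("PlaneImage", pixels = px, oob = matrix(FALSE, n, n),
             plane = orientedPlane(c(0, 0, 0), c(1, 0, 0), n, 1))
  m <- segmentationModel("wall", diameterPriorUm = 33)
  expect_null(selectCenterMask(segmentPlane(img, m), img))
  mOff <- segmentationModel("wall", diameterPriorUm = 33,
                            options = list(eccReject = Inf))
  expect_false(is.null(selectCenterMask(segmentPlane(img, mOff), img)))
})

test_that("an unregistered plugin backend raises a declared failure", {
  img <- diskImage()
  m <- segmentationModel("x", backend = "no-such-plugin", diameterPriorUm = 30)
  expect_error(segmentPlane(img, m), "not registered")
  registerSegmentationBackend("all-ones", function(px, dpPx, opts)
    array(1L, dim = dim(px)))
  out <- segmentPlane(img, segmentationModel("x", backend = "all-ones",
                                             diameterPriorUm = 30))
  expect_true(out@success)
})

test_that("frame selection keeps the first frame and applies all three rules", {
  set.seed(3)
  f1 <- matrix(stats::runif(900), 30)
  distinct <- c(list(f1), lapply(1:5, function(i) matrix(stats::runif(900), 30)))
  p0 <- frameSelectionParams(alpha = 0.05, beta = 0.05, minInterval = 0)
  # identical frames: SSIM change is zero, only the first is kept
  expect_identical(selectTrainingFrames(rep(list(f1), 6), p0), 1L)
  # mutually very different frames are all kept
  expect_identical(selectTrainingFrames(distinct, p0), 1:6)
  # a distinct frame within the minimum interval of a kept one is skipped
  p3 <- frameSelectionParams(alpha = 0.05, beta = 0.05, minInterval = 3)
  kept <- selectTrainingFrames(distinct, p3)
  expect_true(all(diff(kept) >= 3))
  expect_identical(selectTrainingFrames(list(), p0), integer(0))
})

test_that("multi-scale SSIM is 1 for identical frames and below 1 otherwise", {
  set.seed(8)
  x <- matrix(stats::runif(4096), 64)
  expect_equal(msSsim(x, x), 1)
  expect_lt(msSsim(x, matrix(stats::runif(4096), 64)), 0.6)
})
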