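# Phantom generator: geometric ground truth, determinism, rejection rules.

test_that("straight cylinder truth mask matches the analytic volume", {
  spec <- tubePhantomSpec(
    centerline = list(model = "line", start = c(27, 27, 21),
                      direction = c(0, 0, 1), lengthUm = 300),
    radius = list(profile = "constant", radiusUm = 20),
    shape = c(55, 55, 343), seed = 7)
  ph <- makeTubePhantom(spec)
  analytic <- pi * 20^2 * 300
  measured <- sum(maskArray(ph$truth)) * prod(spacing(ph$volume))
  expect_lt(abs(measured - analytic) / analytic, 0.1)
})

test_that("the same spec and seed reproduce the volume bit for bit", {
  spec <- tubePhantomSpec(
    centerline = list(model = "line", start = c(20, 20, 15),
                      direction = c(0, 0, 1), lengthUm = 120),
    radius = list(profile = "constant", radiusUm = 8),
    shape = c(41, 41, 152), seed = 123)
  a <- makeTubePhantom(spec)
  b <- makeTubePhantom(spec)
  expect_identical(intensities(a$volume), intensities(b$volume))
  expect_identical(a$truth@centerline, b$truth@centerline)
})

test_that("helix centerline satisfies its parametric identity", {
  spec <- tubePhantomSpec(
    centerline = list(model = "helix", center = c(15, 81, 81),
                      radiusUm = 50, riseUm = 25, turns = 1.2),
    radius = list(profile = "constant", radiusUm = 10),
    shape = c(240, 162, 162), seed = 3)
  ph <- makeTubePhantom(spec)
  cl <- ph$truth@centerline
  rr <- sqrt((cl$y - 81)^2 + (cl$x - 81)^2)
  expect_lt(max(abs(rr - 50)), 1)   # within one voxel of the cylinder
})

test_that("wall staining reaches the configured contrast level", {
  ph <- straightFixture()
  a <- intensities(ph$volume)
  cl <- ph$truth@centerline
  # distance of each foreground voxel to the axis (straight tube at z=y=27)
  dm <- dim(a)
  rr <- sqrt(outer((seq_len(dm[1]) - 28)^2, (seq_len(dm[2]) - 28)^2, "+"))
  wall <- rr >= 17 & rr <= 19.5   # comfortably inside the bright wall band
  wallMean <- mean(a[, , 200][wall])
  expect_gt(wallMean, 3 * 100 - 3 * 20)   # contrast x background - 3 sd
})

test_that("planted in-lumen nuclei lie strictly inside the truth mask", {
  ph <- cytoFixture()
  nl <- ph$truth@nuclei[ph$truth@nuclei$inLumen, ]
  expect_gt(nrow(nl), 10)
  idx <- round(worldToIndex(ph$volume, as.matrix(nl[, c("z", "y", "x")])))
  expect_true(all(maskArray(ph$truth)[idx]))
})

test_that("a centerline escaping the volume laterally is rejected with a diagnostic", {
  spec <- tubePhantomSpec(
    centerline = list(model = "line", start = c(5, 27, 21),
                      direction = c(0, 0, 1), lengthUm = 100),
    radius = list(profile = "constant", radiusUm = 12),
    shape = c(55, 55, 150), seed = 1)
  expect_error(makeTubePhantom(spec), "laterally")
})

test_that("branching truth records one junction per attachment", {
  ph <- yFixture()
  jn <- ph$truth@junctions
  expect_identical(nrow(jn), 1L)
  expect_identical(jn$kind, "branch")
  bw <- bowFixture()
  expect_identical(sort(bw$truth@junctions$kind), c("branch", "reconnection"))
  # no branch specs -> no junctions
  ph0 <- straightFixture()
  expect_identical(nrow(ph0$truth@junctions), 0L)
})

test_that("wave truth records the planted class runs and rejects overlong patterns", {
  wv <- waveFixture()
  runs <- wv$truth@classes
  expect_identical(nrow(runs), 11L)
  expect_identical(runs$class[1:3],
                   c("dark", "sparse_clusters", "dense_clusters"))
  expect_equal(runs$sEnd - runs$sStart, rep(2000, 11))
  # a single-class pattern yields uniform labels
  expect_identical(unique(truthClassAt(wv$truth, c(100, 1000, 1900))), "dark")
  # extents exceeding the tube length are rejected
  bad <- tubePhantomSpec(
    centerline = list(model = "line", start = c(40, 40, 15),
                      direction = c(0, 0, 1), lengthUm = 500),
    radius = list(profile = "constant", radiusUm = 30),
    spacing = c(5, 5, 5), shape = c(17, 17, 110),
    wave = list(pattern = c("dark", "sparse_clusters"), extentUm = 400),
    seed = 2)
  expect_error(makeWavePhantom(bad), "exceed")
})

test_that("signal gaps suppress the wall over the stated interval", {
  ph <- gapFixture()
  a <- intensities(ph$volume)
  # wall band sampled in and out of the gap (gap covers s in [300, 390])
  inGapSlice <- a[, , round(350 + 12)]
  outSlice <- a[, , round(200 + 12)]
  rr <- sqrt(outer((seq_len(55) - 28)^2, (seq_len(55) - 28)^2, "+"))
  band <- rr >= 12 & rr <= 14.5
  expect_lt(mean(inGapSlice[band]), mean(outSlice[band]) - 100)
})
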