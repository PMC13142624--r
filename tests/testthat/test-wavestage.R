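# Spermatogenic-wave classification, smoothing, wave counting, calibration.

mkFrame <- function(n = 120, bg = 50) matrix(bg, n, n)

diskMask <- function(n = 120, r = 55) {
  c0 <- (n + 1) / 2
  sqrt(outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, "+")) <= r
}

test_that("the hierarchical frame classifier follows its three rules", {
  mask <- diskMask()
  p <- waveClassifierParams(a = 2.5, b = 0.02, c = 86, d = 0.62)
  # uniformly dim frame: nothing above threshold 1
  expect_identical(classifyFrame(mkFrame(), mask, p), "dark")
  # two large blobs holding ~90% of the bright area
  fr <- mkFrame()
  fr[30:55, 30:55] <- 200; fr[70:90, 70:90] <- 200   # two big squares
  fr[20:22, 80:82] <- 200                            # one small speck
  expect_identical(classifyFrame(fr, mask, p), "dense_clusters")
  # many equal specks: the two largest hold far less than d
  fr2 <- mkFrame()
  for (i in seq(25, 95, 14)) for (j in seq(25, 95, 14))
    fr2[i:(i + 2), j:(j + 2)] <- 200
  expect_identical(classifyFrame(fr2, mask, p), "sparse_clusters")
  expect_error(classifyFrame(mkFrame(), mask & FALSE, p), "empty")
})

test_that("frame classification is invariant to in-plane rotation", {
  mask <- diskMask()
  p <- waveClassifierParams()
  fr <- mkFrame()
  fr[30:55, 30:55] <- 200; fr[70:90, 70:90] <- 200
  rot <- fr[rev(seq_len(nrow(fr))), ]          # 180-degree rotation
  rot <- t(rot)[, rev(seq_len(ncol(fr)))]     # -> 90 degrees total
  expect_identical(classifyFrame(fr, mask, p), classifyFrame(rot, mask, p))
})

mkSeq <- function(raw, stepUm = 30) {
  new("StageSequence",
      frames = data.frame(s = (seq_along(raw) - 1) * stepUm, raw = raw,
                          smoothed = NA_character_, stringsAsFactors = FALSE),
      waves = data.frame(startUm = numeric(0), endUm = numeric(0),
                         direction = character(0)),
      reversals = 0L)
}

test_that("modal smoothing removes isolated flips and keeps blocks", {
  blocks <- rep(c("dark", "sparse_clusters", "dense_clusters"), each = 100)
  sq <- mkSeq(blocks)
  sm <- smoothLabels(sq, windowUm = 2000)
  expect_identical(sm@frames$smoothed, blocks)   # constant blocks unchanged
  flip <- blocks; flip[50] <- "dense_clusters"
  smf <- smoothLabels(mkSeq(flip), windowUm = 2000)
  expect_identical(smf@frames$smoothed[50], "dark")
  # block boundaries move by less than half the window
  twoBlocks <- rep(c("dark", "dense_clusters"), each = 150)
  sm2 <- smoothLabels(mkSeq(twoBlocks), windowUm = 2000)
  boundary <- which(sm2@frames$smoothed != "dark")[1]
  expect_lt(abs(sm2@frames$s[boundary] - 150 * 30), 1000)
})

test_that("wave counting follows the cyclic class order", {
  per <- c("dark", "sparse_clusters", "dense_clusters")
  threePeriods <- countWaves(mkSeq(rep(rep(per, each = 20), 3)))
  expect_identical(nrow(threePeriods@waves), 3L)
  expect_identical(threePeriods@reversals, 0L)
  expect_true(all(threePeriods@waves$direction == "forward"))
  # single class: nothing to count
  single <- countWaves(mkSeq(rep("dark", 50)))
  expect_identical(nrow(single@waves), 0L)
  expect_identical(single@reversals, 0L)
  # one period then the sequence runs backwards: one wave, one reversal
  rev1 <- countWaves(mkSeq(rep(c(per, "sparse_clusters", "dark"), each = 20)))
  expect_identical(nrow(rev1@waves), 1L)
  expect_identical(rev1@reversals, 1L)
})

test_that("grid calibration scores every combination and breaks ties downward", {
  mask <- diskMask(40, 18)
  dark <- mkFrame(40); dense <- mkFrame(40); sparse <- mkFrame(40)
  dense[10:20, 10:20] <- 200; dense[25:32, 25:32] <- 200
  for (i in seq(8, 32, 6)) for (j in seq(8, 32, 6)) sparse[i:(i + 1), j:(j + 1)] <- 200
  frames <- list(dark, dense, sparse, dark, dense, sparse)
  labels <- rep(c("dark", "dense_clusters", "sparse_clusters"), 2)
  # grid of size 1 returns that combination
  g1 <- calibrateParams(frames, mask, labels,
                        grids = list(a = 2.5, b = 0.02, c = 86, d = 0.62))
  expect_identical(g1$params@a, 2.5)
  expect_identical(nrow(g1$table), 1L)
  # a perfectly separable set reaches macro-F1 = 1 at its optimum
  g <- calibrateParams(frames, mask, labels,
                       grids = list(a = c(1.5, 2.5), b = c(0.02, 0.1),
                                    c = c(86, 120), d = c(0.3, 0.62)))
  expect_identical(g$macroF1, 1)
  expect_error(calibrateParams(frames, mask, rep("dark", 6),
                               grids = list(a = 1, b = 0.1, c = 5, d = 0.5)),
               "2 classes")
})

test_that("the wave phantom calibrates to its generative thresholds", {
  wv <- waveFixture()
  st <- wv$stack
  truthLab <- truthClassAt(wv$truth, st@arcLengths)
  ok <- which(!is.na(truthLab))
  idx <- ok[seq(1, length(ok), by = 3)]
  frames <- lapply(idx, function(k) st@frames[, , k])
  cal <- calibrateParams(frames, diskMaskUm(st, 110), truthLab[idx],
                         grids = list(a = c(1.5, 2, 2.5, 3),
                                      b = c(0.005, 0.02, 0.1),
                                      c = c(70, 86, 100, 120),
                                      d = c(0.3, 0.62, 0.9)))
  expect_gte(cal$macroF1, 0.95)
  expect_identical(c(cal$params@a, cal$params@b, cal$params@c, cal$params@d),
                   c(2.5, 0.02, 86, 0.62))
})

test_that("classified wave phantom frames recover the planted periods", {
  wv <- waveFixture()
  sq <- classifyStack(wv$stack, waveClassifierParams(), maskRadiusUm = 110)
  sq <- countWaves(smoothLabels(sq, windowUm = 2000))
  expect_identical(nrow(sq@waves), 3L)
  expect_identical(sq@reversals, 1L)
  truthLab <- truthClassAt(wv$truth, wv$stack@arcLengths)
  ok <- !is.na(truthLab)
  expect_gte(mean(sq@frames$smoothed[ok] == truthLab[ok]), 0.9)
})
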