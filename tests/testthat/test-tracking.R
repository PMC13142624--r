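# The tracking engine: adaptive parameters, stepping, rotational search,
# multi-hypothesis consensus, troubleshooting, corrections, stalls.

test_that("adaptive runtime parameters follow the published formulas", {
  cfg <- trackingConfig()
  # published defaults at the initial diameter of 34 um
  rp0 <- updateAdaptiveParams(numeric(0), cfg)
  expect_identical(rp0$dPrime, 34)
  expect_identical(rp0$S, 7)    # round(34/5)
  expect_identical(rp0$J, 11)   # round(34/3)
  expect_identical(rp0$D, 85)   # round(34*2.5)
  rp <- updateAdaptiveParams(rep(34, 12), cfg)
  expect_identical(rp$dPrime, 34)
  # clamping to the physiological bounds
  expect_identical(updateAdaptiveParams(rep(0.5, 3), cfg)$dPrime, 0.8)
  expect_identical(updateAdaptiveParams(rep(99, 3), cfg)$dPrime, 50)
  # running average uses at most the last W diameters
  rpW <- updateAdaptiveParams(c(rep(10, 50), rep(20, cfg@window)), cfg)
  expect_identical(rpW$dPrime, 20)
})

test_that("seed validation rejects bad seed pairs", {
  ph <- straightFixture()
  expect_error(trackTubule(ph$volume, rbind(c(27, 27, 25), c(27, 27, 25)),
                           models = modelSuite()), "coincident")
  expect_error(trackTubule(ph$volume, rbind(c(-5, 27, 25), c(27, 27, 33)),
                           models = modelSuite()), "inside")
})

test_that("node spacing on a straight tube matches the adaptive step size", {
  tr <- straightTrackFixture()
  nd <- trackNodes(tr)
  gaps <- diff(nd$s[-(1:2)])
  # d' converges to ~40 um so S = round(40/5) = 8
  expect_equal(stats::median(gaps), 8, tolerance = 0.05)
  expect_true(all(gaps > 0))
})

test_that("a tube exiting the volume terminates at the face", {
  tr <- straightTrackFixture()
  expect_identical(trackStatus(tr), "terminated_boundary")
  expect_gt(max(trackNodes(tr)$x), 1020)
})

test_that("rotational search evaluates the full sweep and realigns a tilted plane", {
  ph <- straightFixture()
  cfg <- trackingConfig()
  expect_identical(length(seq(-cfg@rotationRange, cfg@rotationRange,
                              by = cfg@rotationStep)), 13L)
  # plane pre-tilted 30 degrees about y at a mid-tube position
  n0 <- c(sin(30 * pi / 180), 0, cos(30 * pi / 180))
  pl <- orientedPlane(center = c(27, 27, 500), normal = n0, side = 100,
                      pitch = 1)
  img <- samplePlane(ph$volume, pl)
  m <- segmentationModel("wall", diameterPriorUm = 40,
                         options = list(eccReject = Inf))
  mask0 <- selectCenterMask(segmentPlane(img, m), img)
  rs <- rotationalSearch(ph$volume, pl, mask0, m, 40, cfg)
  expect_false(is.null(rs))
  expect_lt(rs$mask@ellipse$eccentricity, mask0@ellipse$eccentricity)
  ang <- acos(abs(sum(rs$plane@normal * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 10)
})

test_that("round cross-sections below the trigger never invoke recovery", {
  tr <- straightTrackFixture()
  nd <- trackNodes(tr)
  expect_identical(sum(nd$rotationalSearch), 0L)
  expect_identical(sum(nd$troubleshoot), 0L)
})

test_that("consensus voting honours majority, unanimity and depth persistence", {
  disk <- array(0L, c(9, 9, 10))
  disk[3:7, 3:7, ] <- 1L
  empty <- array(0L, c(9, 9, 10))
  # unanimity
  expect_identical(consensusFromHypotheses(list(disk, disk, disk), 1),
                   disk[, , 1] > 0)
  # 2 of 3 agree, 1 empty (abstains)
  expect_identical(consensusFromHypotheses(list(disk, disk, empty), 1),
                   disk[, , 1] > 0)
  # component on only 2 of 10 slices fails depth persistence
  shallow <- empty
  shallow[3:7, 3:7, 1:2] <- 1L
  expect_null(consensusFromHypotheses(list(shallow, shallow), 1))
  expect_error(consensusFromHypotheses(list(disk), 1), "at least 2")
  expect_error(consensusFromHypotheses(list(disk, disk[, , 1:5, drop = FALSE])),
               "geometry")
})

test_that("consensus equals exhaustive per-pixel majority voting on tiny slabs", {
  bruteConsensus <- function(hyps, tgt = 1) {
    bins <- lapply(hyps, function(h) h > 0)
    d <- dim(bins[[1]])
    cons <- array(FALSE, d)
    for (k in 1:d[3]) {
      active <- Filter(function(b) any(b[, , k]), bins)
      if (length(active) == 0) next
      for (i in 1:d[1]) for (j in 1:d[2]) {
        v <- 0L
        for (b in active) v <- v + b[i, j, k]
        cons[i, j, k] <- v >= length(active) / 2
      }
    }
    if (!any(cons)) return(NULL)
    lab <- array(0L, d)   # brute-force 26-connected labelling by expansion
    nl <- 0L
    for (seed in which(cons)) {
      if (lab[seed] > 0L) next
      nl <- nl + 1L
      lab[seed] <- nl
      repeat {
        changed <- FALSE
        for (v in which(cons & lab == 0L)) {
          vi <- arrayInd(v, d)
          nb <- which(lab > 0L)
          for (w in nb) {
            wi <- arrayInd(w, d)
            if (all(abs(vi - wi) <= 1) && lab[w] == nl) {
              lab[v] <- nl; changed <- TRUE; break
            }
          }
        }
        if (!changed) break
      }
    }
    c0 <- round((d[1] + 1) / 2)
    cl <- lab[c0, c0, tgt]
    if (cl == 0L) return(NULL)
    comp <- lab == cl
    if (sum(apply(comp, 3, any)) < d[3] / 2) return(NULL)
    comp[, , tgt]
  }
  set.seed(99)
  for (p in 1:8) {
    hyps <- lapply(1:3, function(i)
      array(stats::rbinom(75, 1, 0.5), c(5, 5, 3)))
    if (p == 2) hyps[[3]][] <- 0L
    if (p == 3) {
      disk <- array(0L, c(5, 5, 3)); disk[2:4, 2:4, ] <- 1L
      hyps <- list(disk, disk, array(0L, c(5, 5, 3)))
    }
    a <- consensusFromHypotheses(hyps, 1)
    b <- bruteConsensus(hyps, 1)
    if (is.null(a) || is.null(b)) expect_identical(is.null(a), is.null(b))
    else expect_identical(a, b)
  }
})

test_that("the diameter sweep recovers an abrupt 40 to 16 um step", {
  ph <- stepFixture()
  tr <- trackTubule(ph$volume, ph$seeds, trackingConfig(), modelSuite(),
                    id = "step")
  nd <- trackNodes(tr)
  expect_identical(trackStatus(tr), "terminated_boundary")
  expect_identical(nrow(flagQueue(tr)), 0L)
  expect_gte(sum(nd$troubleshoot), 1L)
  # the adopted diameter came from the d' - J sweep arm and the thin limb
  # is then measured at its true calibre
  tsLog <- Filter(function(e) identical(e$module, "TS"), tr@interventionLog)
  expect_gte(length(tsLog), 1L)
  expect_lt(tsLog[[1]]$diameter, 34)
  expect_equal(utils::tail(nd$diameter, 1), 16, tolerance = 0.05)
})

test_that("with troubleshooting disabled the step flags into the queue", {
  ph <- stepFixture()
  tr <- trackTubule(ph$volume, ph$seeds, trackingConfig(enableTS = FALSE),
                    modelSuite(), id = "step_nots")
  expect_identical(trackStatus(tr), "flagged")
  fq <- flagQueue(tr)
  expect_identical(fq$reason, "no_mask_any_model")
  # the flag snapshot carries the runtime parameters at failure
  expect_true(all(c("S", "J", "D", "dPrime") %in% names(fq)))
  expect_equal(fq$dPrime, 40, tolerance = 0.05)
})

test_that("troubleshooting failure in a signal gap produces exactly one flag", {
  ph <- gapFixture()
  tr <- trackTubule(ph$volume, ph$seeds, trackingConfig(), modelSuite(),
                    id = "gap")
  expect_identical(trackStatus(tr), "flagged")
  expect_identical(nrow(flagQueue(tr)), 1L)
  # conservation: the failure produced a flag, not a silent drop
  expect_identical(flagQueue(tr)$reason, "no_mask_any_model")
})

test_that("a one-click correction past a dropout resumes and completes", {
  ph <- gapFixture()
  tr <- trackTubule(ph$volume, ph$seeds, trackingConfig(), modelSuite(),
                    id = "gap")
  nLog <- length(tr@interventionLog)
  tr2 <- applyCorrection(tr, c(27, 27, 420), resume = TRUE,
                         volume = ph$volume, models = modelSuite())
  expect_identical(trackStatus(tr2), "terminated_boundary")
  expect_gt(max(trackNodes(tr2)$x), 650)
  expect_identical(sum(trackNodes(tr2)$manualCorrection), 1L)
  expect_gte(length(tr2@interventionLog), nLog + 1L)
  # corrections only apply to flagged tracks
  expect_error(applyCorrection(tr2, c(27, 27, 500)), "flagged")
  # a correction point outside the volume is rejected
  expect_error(applyCorrection(tr, c(-10, 27, 420), volume = ph$volume),
               "outside")
})

test_that("identical configuration and seeds give bit-identical tracks", {
  ph <- stepFixture()
  a <- trackTubule(ph$volume, ph$seeds, trackingConfig(), modelSuite(), id = "a")
  b <- trackTubule(ph$volume, ph$seeds, trackingConfig(), modelSuite(), id = "b")
  expect_identical(trackNodes(a)[, names(trackNodes(a)) != "model"],
                   trackNodes(b)[, names(trackNodes(b)) != "model"])
  expect_identical(trackNodes(a), trackNodes(b))
})

test_that("recovery bookkeeping is conserved: every failure ends in success or a flag", {
  for (tr in list(straightTrackFixture(),
                  trackTubule(stepFixture()$volume, stepFixture()$seeds,
                              trackingConfig(), modelSuite(), id = "s"),
                  trackTubule(gapFixture()$volume, gapFixture()$seeds,
                              trackingConfig(), modelSuite(), id = "g"))) {
    nd <- trackNodes(tr)
    recovered <- sum(nd$troubleshoot) + sum(nd$rotationalSearch)
    logged <- length(tr@interventionLog)
    expect_identical(recovered, logged)
    if (trackStatus(tr) == "flagged") expect_identical(nrow(flagQueue(tr)), 1L)
    else expect_identical(nrow(flagQueue(tr)), 0L)
  }
})
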