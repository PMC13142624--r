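# Curvature/torsion estimators, loop typing, segment summaries, tracking
# evaluation.

test_that("curvature and torsion match closed forms on parametric curves", {
  # straight line: both vanish
  lin <- cbind(seq(0, 500, 5), 0, 0)
  pl <- morphometricProfiles(lin, stepUm = 5)
  expect_lt(max(pl$curvature, na.rm = TRUE), 1e-9)
  expect_lt(max(abs(pl$torsion), na.rm = TRUE), 1e-9)
  # circle R = 100: kappa = 1/R, tau = 0
  th <- seq(0, 2 * pi, length.out = 2000)
  circ <- cbind(0, 100 * sin(th), 100 * cos(th))
  pc <- morphometricProfiles(circ, stepUm = 2)
  expect_equal(mean(pc$curvature, na.rm = TRUE), 0.01, tolerance = 0.05)
  expect_lt(mean(abs(pc$torsion), na.rm = TRUE), 5e-4)
  # helix R = 50, c = 25: kappa = R/(R^2+c^2), |tau| = c/(R^2+c^2)
  tt <- seq(0, 6 * pi, length.out = 3000)
  hel <- cbind(25 * tt, 50 * sin(tt), 50 * cos(tt))
  phl <- morphometricProfiles(hel, stepUm = 2)
  expect_equal(mean(phl$curvature, na.rm = TRUE), 50 / 3125, tolerance = 0.05)
  expect_equal(mean(abs(phl$torsion), na.rm = TRUE), 25 / 3125,
               tolerance = 0.05)
  expect_error(morphometricProfiles(lin[1:3, ]), "at least 4")
})

test_that("estimates converge monotonically as the resampling step shrinks", {
  th <- seq(0, 2 * pi, length.out = 4000)
  circ <- cbind(0, 100 * sin(th), 100 * cos(th))
  errsK <- vapply(c(20, 10, 5), function(h)
    abs(mean(morphometricProfiles(circ, stepUm = h, smooth = FALSE)$curvature,
             na.rm = TRUE) - 0.01), 0)
  # the circumradius of exact circle samples is exact at any step
  expect_true(all(errsK < 1e-6))
  tt <- seq(0, 6 * pi, length.out = 6000)
  hel <- cbind(25 * tt, 50 * sin(tt), 50 * cos(tt))
  errsT <- vapply(c(20, 10, 5), function(h)
    abs(mean(abs(morphometricProfiles(hel, stepUm = h, smooth = FALSE)$torsion),
             na.rm = TRUE) - 25 / 3125), 0)
  expect_true(all(diff(errsT) < 0))
})

test_that("profiles are invariant to rigid rotation of the track", {
  tt <- seq(0, 4 * pi, length.out = 2000)
  hel <- cbind(25 * tt, 50 * sin(tt), 50 * cos(tt))
  ax <- c(1, 2, 0.5) / sqrt(5.25)
  rot <- t(apply(hel, 1, function(p)
    p * cos(0.7) + c(ax[2] * p[3] - ax[3] * p[2],
                     ax[3] * p[1] - ax[1] * p[3],
                     ax[1] * p[2] - ax[2] * p[1]) * sin(0.7) +
      ax * sum(ax * p) * (1 - cos(0.7))))
  a <- morphometricProfiles(hel, stepUm = 3)
  b <- morphometricProfiles(rot, stepUm = 3)
  expect_equal(mean(a$curvature, na.rm = TRUE), mean(b$curvature, na.rm = TRUE),
               tolerance = 0.01)
  expect_equal(mean(abs(a$torsion), na.rm = TRUE),
               mean(abs(b$torsion), na.rm = TRUE), tolerance = 0.01)
})

test_that("loop type follows the thin-limb length and inner-medulla rules", {
  expect_identical(classifyLoopType(thinLimbLengthUm = 800)$class, "SLN")
  expect_identical(classifyLoopType(thinLimbLengthUm = 2000)$class, "LLN")
  byRegion <- classifyLoopType(regionLabels = c("cortex", "OSOM", "IM"))
  expect_identical(byRegion$class, "LLN")
  expect_identical(byRegion$rule, "region")
  both <- classifyLoopType(thinLimbLengthUm = 800,
                           regionLabels = c("cortex", "OSOM"))
  expect_identical(both$rule, "both")
  expect_identical(both$class, "SLN")
  expect_error(classifyLoopType(), "thin-limb length or region labels")
})

test_that("segment summaries recover planted per-segment calibres", {
  # profile with three segments at 40 / 16 / 24 um
  s <- seq(0, 3000, 5)
  d <- ifelse(s < 1000, 40, ifelse(s < 2000, 16, 24)) +
    stats::rnorm(length(s), 0, 0.5)
  profile <- data.frame(s = s, diameter = d, curvature = 0, torsion = 0)
  ann <- data.frame(sStart = c(0, 1005, 2005), sEnd = c(995, 1995, 3000),
                    label = c("PCT", "thin_limb", "thick_limb"))
  sm <- segmentSummary(profile, ann)
  expect_equal(sm$meanDiameter, c(40, 16, 24), tolerance = 0.05)
  # one segment covering everything equals whole-profile statistics
  all1 <- segmentSummary(profile, data.frame(sStart = 0, sEnd = 3000,
                                             label = "all"))
  expect_equal(all1$meanDiameter, mean(d), tolerance = 1e-6)
  expect_identical(nrow(segmentSummary(profile, ann[0, ])), 0L)
  expect_warning(segmentSummary(profile,
                                data.frame(sStart = 5000, sEnd = 6000,
                                           label = "void")), "empty")
})

test_that("a clean run counts zero breaks and one full uninterrupted length", {
  ph <- straightFixture()
  ev <- evaluateTracking(ph$volume, ph$truth@centerline,
                         config = trackingConfig(), models = modelSuite())
  expect_identical(ev$breaks, 0L)
  expect_length(ev$uninterruptedLengthsUm, 1)
  L <- max(ph$truth@centerline$s)
  expect_gt(ev$uninterruptedLengthsUm, 0.85 * L)
  expect_lte(sum(ev$uninterruptedLengthsUm), L + 50)
})

test_that("a planted dropout with recovery disabled forces at least one break", {
  ph <- gapFixture()
  ev <- evaluateTracking(ph$volume, ph$truth@centerline,
                         config = trackingConfig(enableTS = FALSE),
                         models = modelSuite())
  expect_gte(ev$breaks, 1L)
  L <- max(ph$truth@centerline$s)
  expect_lte(sum(ev$uninterruptedLengthsUm), L + 50)
})
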