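# Shared phantom fixtures, built lazily and cached for the whole test run.
# All study conditions (sizes, contrasts, noise levels) are fixed here once;
# see the methods vignette for the rationale behind each regime.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

modelSuite <- function() list(
  segmentationModel("wall", "builtin-threshold"),
  segmentationModel("lumen", "builtin-lumen"))

# 1 mm straight tube, r = 20 um, 1 um isotropic, cortex-quality staining;
# runs out through the +x face so tracking terminates at the boundary.
straightFixture <- function() fixture("straight", function() {
  spec <- tubePhantomSpec(
    centerline = list(model = "line", start = c(27, 27, 21),
                      direction = c(0, 0, 1), lengthUm = 1030),
    radius = list(profile = "constant", radiusUm = 20),
    intensity = list(contrast = 3, background = 100, wallThicknessUm = 4),
    noiseSd = 20, shape = c(55, 55, 1043), seed = 7)
  c(makeTubePhantom(spec), list(spec = spec, seeds = rbind(c(27, 27, 25),
                                                           c(27, 27, 33))))
})

straightTrackFixture <- function() fixture("straightTrack", function() {
  ph <- straightFixture()
  trackTubule(ph$volume, ph$seeds, trackingConfig(), modelSuite(),
              id = "straight")
})

# 40 -> 16 um abrupt diameter step (proximal-to-thin-limb transition).
stepFixture <- function() fixture("step", function() {
  spec <- tubePhantomSpec(
    centerline = list(model = "line", start = c(27, 27, 12),
                      direction = c(0, 0, 1), lengthUm = 810),
    radius = list(profile = "steps",
                  breaks = data.frame(sUm = c(0, 380), radiusUm = c(20, 8))),
    intensity = list(contrast = 3, background = 100, wallThicknessUm = 4),
    noiseSd = 15, shape = c(55, 55, 820), seed = 9)
  c(makeTubePhantom(spec), list(seeds = rbind(c(27, 27, 16), c(27, 27, 24))))
})

# Convoluted sharp-bend phantom: serpentine with ~90 degree vertices spaced
# 90 um (3 tube diameters), mildly anisotropic axial sampling, deep-tissue
# staining contrast.
zigzagFixture <- function() fixture("zigzag", function() {
  segLen <- 90; y0 <- 25
  p <- c(70, y0, 12); dirAng <- 0
  pts <- matrix(p, 1)
  for (i in seq_len(7)) {
    dirv <- c(sin(dirAng), 0, cos(dirAng))
    p <- p + segLen * dirv
    pts <- rbind(pts, p)
    dirAng <- dirAng + (if (i %% 2 == 1) 1 else -1) * 90 * pi / 180
  }
  spec <- tubePhantomSpec(
    centerline = list(model = "polyline", points = pts),
    radius = list(profile = "constant", radiusUm = 15),
    intensity = list(contrast = 2, background = 100, wallThicknessUm = 8),
    noiseSd = 20, spacing = c(2, 1, 1),
    shape = c(ceiling((max(pts[, 1]) + 40) / 2), 51,
              ceiling(max(pts[, 3]) + 40)),
    seed = 31)
  makeTubePhantom(spec)
})

# Smooth U-turn with radius of curvature 3x tube diameter (the easy regime).
smoothBendFixture <- function() fixture("smoothBend", function() {
  spec <- tubePhantomSpec(
    centerline = list(model = "arc", start = c(30, 25, 18),
                      direction = c(0, 0, 1), axis = c(0, 1, 0),
                      radiusUm = 90, angleDeg = 180,
                      straightBeforeUm = 110, straightAfterUm = 135),
    radius = list(profile = "constant", radiusUm = 15),
    intensity = list(contrast = 2, background = 100, wallThicknessUm = 8),
    noiseSd = 20, spacing = c(3, 1, 1), shape = c(85, 51, 240), seed = 21)
  makeTubePhantom(spec)
})

# Seminiferous-scale wave phantom: 3 complete dark/sparse/dense periods then
# a reversed half-period, 2 mm per class run.
waveFixture <- function() fixture("wave", function() {
  pattern <- c(rep(c("dark", "sparse_clusters", "dense_clusters"), 3),
               "sparse_clusters", "dark")
  spec <- tubePhantomSpec(
    centerline = list(model = "line", start = c(125, 125, 30),
                      direction = c(0, 0, 1), lengthUm = 22200),
    radius = list(profile = "constant", radiusUm = 110),
    intensity = list(background = 40),
    noiseSd = 5, spacing = c(5, 5, 5), shape = c(51, 51, 4460),
    wave = list(pattern = pattern, extentUm = 2000), seed = 42)
  ph <- makeWavePhantom(spec)
  st <- straightenTubule(ph$volume,
                         as.matrix(ph$truth@centerline[, c("z", "y", "x")]),
                         intervalUm = 30, sideUm = 2.3 * 220)
  c(ph, list(stack = st))
})

# 2 mm tube with planted nuclei: in-lumen planting rate 0.5 per 20 um.
cytoFixture <- function() fixture("cyto", function() {
  spec <- tubePhantomSpec(
    centerline = list(model = "line", start = c(32, 32, 10),
                      direction = c(0, 0, 1), lengthUm = 2012),
    radius = list(profile = "constant", radiusUm = 20),
    intensity = list(contrast = 3, background = 100, wallThicknessUm = 4),
    noiseSd = 15, spacing = c(2, 2, 2), shape = c(33, 33, 1010),
    nuclei = list(densityPerUm = 0.0333, radiusUm = 4,
                  inLumenFraction = 0.75),
    seed = 11)
  c(makeTubePhantom(spec), list(seeds = rbind(c(32, 32, 14), c(32, 32, 22))))
})

cytoTrackFixture <- function() fixture("cytoTrack", function() {
  ph <- cytoFixture()
  tr <- trackTubule(ph$volume, ph$seeds, trackingConfig(), modelSuite(),
                    id = "cyto")
  rec <- interpolateCrossSections(tr, ph$volume)
  list(track = tr, reconstruction = rec)
})

# Y-branch phantom (steep 75-degree take-off) and its two tracks.
yFixture <- function() fixture("y", function() {
  ang <- 75 * pi / 180
  child <- tubePhantomSpec(
    centerline = list(model = "line", start = c(0, 0, 0),
                      direction = c(sin(ang), 0, cos(ang)), lengthUm = 230),
    radius = list(profile = "constant", radiusUm = 14),
    intensity = list(contrast = 3, background = 100, wallThicknessUm = 4),
    shape = c(2, 2, 2))
  spec <- tubePhantomSpec(
    centerline = list(model = "line", start = c(30, 30, 12),
                      direction = c(0, 0, 1), lengthUm = 680),
    radius = list(profile = "constant", radiusUm = 14),
    intensity = list(contrast = 3, background = 100, wallThicknessUm = 4),
    noiseSd = 15, shape = c(280, 61, 690),
    branches = list(list(attachS = 300, spec = child)),
    seed = 5)
  makeBranchingPhantom(spec)
})

# Branch that later rejoins the main tube (reconnection case).
bowFixture <- function() fixture("bow", function() {
  bow <- tubePhantomSpec(
    centerline = list(model = "polyline",
                      points = rbind(c(0, 0, 0), c(70, 0, 30), c(90, 0, 125),
                                     c(70, 0, 220), c(0, 0, 250))),
    radius = list(profile = "constant", radiusUm = 14),
    intensity = list(contrast = 3, background = 100, wallThicknessUm = 4),
    shape = c(2, 2, 2))
  spec <- tubePhantomSpec(
    centerline = list(model = "line", start = c(30, 30, 12),
                      direction = c(0, 0, 1), lengthUm = 680),
    radius = list(profile = "constant", radiusUm = 14),
    intensity = list(contrast = 3, background = 100, wallThicknessUm = 4),
    noiseSd = 15, shape = c(140, 61, 690),
    branches = list(list(attachS = 200, spec = bow, reconnectS = 450)),
    seed = 6)
  makeBranchingPhantom(spec)
})

# Signal-dropout phantom: wall staining absent over s in [300, 390] um.
gapFixture <- function() fixture("gap", function() {
  spec <- tubePhantomSpec(
    centerline = list(model = "line", start = c(27, 27, 12),
                      direction = c(0, 0, 1), lengthUm = 700),
    radius = list(profile = "constant", radiusUm = 15),
    intensity = list(contrast = 3, background = 100, wallThicknessUm = 4),
    noiseSd = 15, shape = c(55, 55, 700),
    gaps = list(c(300, 390)), seed = 13)
  c(makeTubePhantom(spec), list(seeds = rbind(c(27, 27, 16), c(27, 27, 24))))
})

# Four parallel tubes in one volume for parallel/determinism checks.
multiFixture <- function() fixture("multi", function() {
  ys <- c(30, 80, 130, 180)
  specs <- lapply(ys, function(y) tubePhantomSpec(
    centerline = list(model = "line", start = c(25, y, 10),
                      direction = c(0, 0, 1), lengthUm = 420),
    radius = list(profile = "constant", radiusUm = 14),
    intensity = list(contrast = 3, background = 100, wallThicknessUm = 4),
    noiseSd = 15, shape = c(50, 210, 430), seed = 17))
  mp <- makeMultiTubePhantom(specs)
  seeds <- lapply(seq_along(ys), function(i)
    list(id = paste0("tube", i), seed1_zyx_um = c(25, ys[i], 14),
         seed2_zyx_um = c(25, ys[i], 22)))
  c(mp, list(seeds = seeds))
})

# Disk mask covering the tubule cross-section in a straightened stack frame.
diskMaskUm <- function(stack, radiusUm) {
  d <- dim(stack@frames)
  c0 <- (d[1] + 1) / 2
  pitch <- stack@planes[[1]]@pitch
  sqrt(outer((seq_len(d[1]) - c0)^2, (seq_len(d[2]) - c0)^2, "+")) * pitch <=
    radiusUm
}
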