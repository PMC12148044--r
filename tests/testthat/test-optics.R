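test_that("tilt phase factor follows 4*pi*tan(alpha)/lambda", {
  expect_identical(phaseFactor(0, 532e-9), 0)
  expect_equal(phaseFactor(1e-6, 532e-9), 4 * pi * 1e-6 / 532e-9)
  # odd symmetry and small-angle linearization
  for (a in c(1e-7, 1e-5, 1e-3, 0.3)) {
    expect_equal(phaseFactor(-a, 532e-9), -phaseFactor(a, 532e-9))
  }
  for (a in c(1e-6, 1e-4, 1e-3)) {
    lin <- 4 * pi * a / 532e-9
    expect_lt(abs(phaseFactor(a, 532e-9) - lin) / lin, 1e-6)
  }
  expect_error(phaseFactor(NaN, 532e-9))
  expect_error(phaseFactor(1.6, 532e-9))
  expect_error(phaseFactor(1e-3, -1))
})

test_that("far-field minimum distance is D^2/(4 lambda)", {
  expect_equal(farFieldMinDistance(1e-3, 532e-9), 1e-6 / (4 * 532e-9))
  expect_equal(farFieldMinDistance(1e-3, 532e-9), 0.46992, tolerance = 1e-4)
  expect_equal(farFieldMinDistance(2e-3, 532e-9),
               4 * farFieldMinDistance(1e-3, 532e-9))
  expect_error(farFieldMinDistance(0, 532e-9))
  expect_error(farFieldMinDistance(1e-3, 0))
  # the default geometry violates the literal bound; construction warns
  expect_warning(opticalConfig(), "far-field")
})

test_that("required focal length is K dx Z3 D / (Z2 lambda)", {
  unitCfg <- suppressWarnings(opticalConfig(
    wavelength = 1, spotDiameter = 1, z2 = 1, z3 = 1, pixelPitch = 1,
    minPixelsPerSpeckle = 1))
  expect_equal(requiredFocalLength(unitCfg), 1)
  cfg <- suppressWarnings(opticalConfig(
    wavelength = 532e-9, spotDiameter = 1e-2, z2 = 0.2, z3 = 55e-3,
    pixelPitch = 3.45e-6, minPixelsPerSpeckle = 2))
  expect_equal(requiredFocalLength(cfg),
               2 * 3.45e-6 * 55e-3 * 1e-2 / (0.2 * 532e-9))
  cfg2 <- suppressWarnings(opticalConfig(
    wavelength = 532e-9, spotDiameter = 1e-2, z2 = 0.4, z3 = 55e-3,
    pixelPitch = 3.45e-6, minPixelsPerSpeckle = 2))
  expect_equal(requiredFocalLength(cfg2), requiredFocalLength(cfg) / 2)
})

test_that("power density divides power by the circular spot area", {
  # 4.5 mW over a 10 mm spot (~78.5 mm^2) is ~0.057 mW/mm^2
  expect_equal(powerDensity(4.5, 1e-2), 4.5 / (pi * 25), tolerance = 1e-12)
  expect_equal(powerDensity(4.5, 1e-2), 0.057, tolerance = 0.01)
  expect_identical(powerDensity(0, 1e-2), 0)
  expect_equal(powerDensity(4.5, 0.5e-2), 4 * powerDensity(4.5, 1e-2))
  expect_error(powerDensity(4.5, 0))
  expect_error(powerDensity(-1, 1e-2))
})

test_that("phase screens are seeded, uniform and grain-calibrated", {
  s1 <- makePhaseScreen(c(64L, 64L), 0.1, seed = 11)
  s2 <- makePhaseScreen(c(64L, 64L), 0.1, seed = 11)
  expect_identical(s1@phase, s2@phase)
  expect_false(identical(
    s1@phase, makePhaseScreen(c(64L, 64L), 0.1, seed = 12)@phase))
  # uniform phases on [0, 2*pi) inside the aperture
  big <- makePhaseScreen(c(256L, 256L), 0.5, seed = 1)
  ph <- big@phase[big@aperture]
  expect_gte(length(ph), 1e4)
  ks <- suppressWarnings(stats::ks.test(ph[seq_len(1e4)], "punif", 0, 2 * pi))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(big@phase[!big@aperture] == 0))
  expect_error(makePhaseScreen(c(64L, 64L), 0.02, seed = 1), "16")
})

test_that("halving the aperture fraction doubles the speckle grain", {
  cfg <- fixtureOptics()
  sizeAt <- function(frac) {
    median(vapply(1:20, function(s) {
      scr <- makePhaseScreen(c(128L, 64L), frac, seed = 100 + s)
      measureSpeckleSize(renderFrame(scr, c(0, 0), cfg))
    }, numeric(1)))
  }
  a <- apertureFractionFor(8)
  expect_equal(sizeAt(a / 2) / sizeAt(a), 2, tolerance = 0.15)
})

test_that("rendering obeys the Fourier shift theorem", {
  cfg <- fixtureOptics()
  scr <- fixtureScreen()
  f0 <- fixtureRefFrame()
  # zero tilt, zero noise reproduces the reference exactly
  expect_identical(renderFrame(scr, c(0, 0), cfg), f0)
  # integer-cycle ramps: exact circular pixel shifts, bit-identical
  f3 <- renderFrame(scr, c(tiltForPx(3, cfg), 0), cfg)
  expect_identical(f3, circShift(f0, 0, 3))
  fd <- renderFrame(scr, c(tiltForPx(3, cfg), tiltForPx(-2, cfg)), cfg)
  expect_identical(fd, circShift(f0, -2, 3))
  # half-cycle ramp lands at 0.5 px by subpixel cross-correlation
  fh <- renderFrame(scr, c(tiltForPx(0.5, cfg), 0), cfg)
  d <- frameCrossCorrelation(f0, fh, upsample = 20)
  expect_equal(unname(d["dx"]), 0.5, tolerance = 0.05)
  expect_equal(unname(d["dy"]), 0.0, tolerance = 0.05)
  expect_error(renderFrame(makePhaseScreen(c(32L, 32L), 0.2, 1),
                           c(0, 0), cfg), "shape")
})

test_that("mean frame intensity is invariant to tilt (energy sanity)", {
  cfg <- fixtureOptics()
  scr <- fixtureScreen()
  m0 <- mean(fixtureRefFrame())
  for (px in c(1.3, 5.7, -3.2)) {
    mt <- mean(renderFrame(scr, c(tiltForPx(px, cfg), 0), cfg))
    expect_equal(mt, m0, tolerance = 0.01)
  }
})

test_that("videos are deterministic and propagate tilt per frame", {
  cfg <- fixtureOptics()
  scr <- fixtureScreen()
  still <- new("TiltSeries", alphaX = numeric(5), alphaY = numeric(5),
               fps = 500)
  v <- synthesizeVideo(still, scr, cfg, noise = NULL)
  expect_equal(dim(v@frames)[3], 5)
  for (t in 2:5) expect_identical(v@frames[, , t], v@frames[, , 1])
  # frame count equals duration * fps
  p <- defaultClassParams(1)$clear
  ts <- generateTiltSeries(p, durationS = 0.3, fps = 500, seed = 1)
  expect_length(ts@alphaX, 150)
  # identical seeds give bit-identical noisy videos
  ramp <- new("TiltSeries", alphaX = seq(0, 4e-4, length.out = 6),
              alphaY = numeric(6), fps = 500)
  v1 <- synthesizeVideo(ramp, scr, cfg, seed = 9)
  v2 <- synthesizeVideo(ramp, scr, cfg, seed = 9)
  expect_identical(v1@frames, v2@frames)
  expect_false(identical(
    v1@frames, synthesizeVideo(ramp, scr, cfg, seed = 10)@frames))
})

test_that("speckle size estimator matches a Gaussian autocorrelation oracle", {
  # Gaussian blob of image FWHM 5 px has autocorrelation FWHM 5*sqrt(2)
  n <- 128
  sigma <- 5 / (2 * sqrt(2 * log(2)))
  rr <- outer((1:n) - n / 2, rep(1, n)) ; cc <- t(rr)
  blob <- exp(-(rr^2 + cc^2) / (2 * sigma^2))
  expect_equal(measureSpeckleSize(blob), 5 * sqrt(2), tolerance = 0.15)
  # scale and offset invariance
  expect_equal(measureSpeckleSize(7 * blob + 3), measureSpeckleSize(blob))
  expect_error(measureSpeckleSize(matrix(1, 32, 32)), "constant")
})

test_that("default configuration renders ~16 px speckle", {
  sizes <- vapply(1:5, function(s) {
    scr <- makePhaseScreen(c(128L, 64L), apertureFractionFor(16),
                           seed = 200 + s)
    measureSpeckleSize(renderFrame(scr, c(0, 0), fixtureOptics()))
  }, numeric(1))
  expect_equal(median(sizes), 16, tolerance = 3 / 16)
})
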