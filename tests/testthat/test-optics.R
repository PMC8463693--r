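test_that("polarization states have a consistent Stokes representation", {
  cases <- list(c(0, 0), c(30, 20), c(175, -44), c(90, 45))
  for (cs in cases) {
    s <- stokes(PolarizationState(azimuth = cs[1], ellipticity = cs[2]))
    expect_equal(s[["S1"]]^2 + s[["S2"]]^2 + s[["S3"]]^2, s[["S0"]]^2,
                 tolerance = 1e-12)
  }
  ## circular states report azimuth 0 by convention
  expect_equal(azimuth(PolarizationState(azimuth = 73, ellipticity = 45)), 0)
  expect_error(PolarizationState(intensity = -1), "intensity")
  expect_error(PolarizationState(ellipticity = 50), "ellipticity")
})

test_that("the spectral fan maps wavelength linearly onto azimuth", {
  fan <- SpectralFan()
  expect_equal(azimuth(fanState(fan, 400)), 0)
  expect_equal(azimuth(fanState(fan, 550)), 90)
  expect_equal(ellipticity(fanState(fan, 550)), 40)
  expect_equal(intensity(fanState(fan, 625)), 1)
  fan90 <- SpectralFan(offset = 90)
  expect_equal(azimuth(fanState(fan90, 400)), 90)
  expect_equal(azimuth(fanState(fan90, 550)), 0)  # wraps mod 180
  expect_error(fanState(fan, 380), "outside")
  expect_error(SpectralFan(offset = 45), "offset")
})

test_that("retarder action reproduces the 10-degree particle worked example", {
  ret <- Retarder(10, 45)
  ## the component whose azimuth maximizes the ellipticity gain reaches
  ## right-circular (+45) and is extinguished by the left analyzer
  up <- applyRetarder(PolarizationState(azimuth = 0, ellipticity = 40), ret)
  expect_equal(ellipticity(up), 45, tolerance = 0.5)
  expect_lt(analyzerTransmission(up, "left"), 1e-12)
  ## the orthogonal component loses the same 5 degrees
  down <- applyRetarder(PolarizationState(azimuth = 90, ellipticity = 40),
                        ret)
  expect_equal(ellipticity(down), 35, tolerance = 0.5)
  ## and its transmission rises about 4-fold over the unperturbed fan
  t0 <- analyzerTransmission(PolarizationState(ellipticity = 40), "left")
  expect_equal(analyzerTransmission(down, "left") / t0, 3.9696,
               tolerance = 1e-3)
  ## zero retardance is the identity
  s <- PolarizationState(azimuth = 123, ellipticity = -17)
  s2 <- applyRetarder(s, Retarder(0, 77))
  expect_equal(azimuth(s2), 123, tolerance = 1e-9)
  expect_equal(ellipticity(s2), -17, tolerance = 1e-9)
})

test_that("retarder action agrees with an independent Jones-matrix oracle", {
  set.seed(42)
  for (i in seq_len(1000)) {
    chi <- runif(1, -44.5, 44.5)
    th <- runif(1, 0, 180)
    d <- runif(1, 0, 180)
    a <- runif(1, 0, 180)
    want <- oracleRetarderStokes(chi, th, d, a)
    got <- stokes(applyRetarder(PolarizationState(1, th, chi),
                                Retarder(d, a)))
    expect_equal(unname(got), want, tolerance = 1e-9)
  }
})

test_that("retarders preserve intensity", {
  set.seed(7)
  for (i in seq_len(50)) {
    s <- PolarizationState(runif(1, 0.1, 5), runif(1, 0, 180),
                           runif(1, -44, 44))
    out <- applyRetarder(s, Retarder(runif(1, 0, 360), runif(1, 0, 180)))
    expect_equal(intensity(out), intensity(s), tolerance = 1e-12)
  }
})

test_that("circular analyzer transmissions are complementary and correct", {
  ## right-circular light is extinguished completely by the left analyzer
  rc <- PolarizationState(ellipticity = 45)
  expect_equal(analyzerTransmission(rc, "left"), 0, tolerance = 1e-15)
  expect_equal(analyzerTransmission(rc, "right"), 1, tolerance = 1e-15)
  ## the fan state at +40 degrees leaks a small fraction
  s40 <- PolarizationState(ellipticity = 40)
  expect_equal(analyzerTransmission(s40, "left"), (1 - sin(80 * pi / 180)) / 2,
               tolerance = 1e-12)
  expect_equal(analyzerTransmission(s40, "left"), 0.00760, tolerance = 1e-3)
  ## energy conservation for arbitrary states
  set.seed(3)
  for (i in seq_len(50)) {
    s <- PolarizationState(1, runif(1, 0, 180), runif(1, -45, 45))
    expect_identical(analyzerTransmission(s, "left") +
                       analyzerTransmission(s, "right"), 1)
  }
})

test_that("pixel rendering reproduces the green/red complementary colours", {
  fan0 <- SpectralFan()
  fan90 <- SpectralFan(offset = 90)
  cam <- gaussianCamera(fan0)
  ## no birefringence: neutral gray at the configured level
  expect_equal(unname(renderPixel(fan0, Retarder(0, 0), cam)),
               rep(0.2, 3), tolerance = 1e-12)
  ## the 10-degree particle at 45 degrees is mostly green under offset 0
  px <- renderPixel(fan0, Retarder(10, 45), cam)
  expect_gt(px[["G"]], px[["R"]])
  expect_gt(px[["G"]], px[["B"]])
  ## and the complementary fan makes it mostly red
  px90 <- renderPixel(fan90, Retarder(10, 45), cam)
  expect_gt(px90[["R"]], px90[["G"]])
  ## mismatched spectral grids are rejected
  camBad <- gaussianCamera(SpectralFan(nSamples = 21L))
  expect_error(renderPixel(fan0, Retarder(10, 45), camBad), "grid")
})

test_that("rotating the fan by 90 degrees equals rotating the sample", {
  fan0 <- SpectralFan()
  fan90 <- SpectralFan(offset = 90)
  cam <- gaussianCamera(fan0)
  for (a in c(0, 17, 45, 120)) {
    for (d in c(3, 10, 25)) {
      pxFan <- renderPixel(fan90, Retarder(d, a), cam)
      pxSample <- renderPixel(fan0, Retarder(d, (a + 90) %% 180), cam)
      expect_equal(pxFan, pxSample, tolerance = 1e-9)
    }
  }
})

test_that("rendering is 180-degree periodic in the sample fast axis", {
  fan <- SpectralFan()
  cam <- gaussianCamera(fan)
  for (a in c(5, 60, 140))
    expect_equal(renderPixel(fan, Retarder(12, a), cam),
                 renderPixel(fan, Retarder(12, a + 180), cam),
                 tolerance = 1e-12)
})

test_that("differential hue depends on the fiber axis, not retardance", {
  fan0 <- SpectralFan()
  fan90 <- SpectralFan(offset = 90)
  cam <- gaussianCamera(fan0)
  diffHue <- function(delta, alpha) {
    d <- renderPixel(fan0, Retarder(delta, alpha), cam) -
      renderPixel(fan90, Retarder(delta, alpha), cam)
    hueAngle(pmax(d, 0))
  }
  for (a in c(20, 45, 100, 160)) {
    hues <- vapply(c(1, 5, 10, 15), diffHue, numeric(1), alpha = a)
    expect_lt(max(hueDiff(hues, hues[1])), 5)
  }
})

test_that("camera model enforces its spectral grid invariants", {
  fan <- SpectralFan()
  cam <- gaussianCamera(fan)
  wl <- fanWavelengths(fan)
  ## each sensitivity curve integrates to one (trapezoid rule)
  for (k in 1:3) {
    s <- cam@sensitivities[, k]
    n <- length(wl)
    integral <- sum(diff(wl) * (s[-1] + s[-n]) / 2)
    expect_equal(integral, 1, tolerance = 1e-9)
  }
  expect_error(CameraModel(wl, matrix(0, length(wl), 3)), "positive area")
})
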