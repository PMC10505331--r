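test_that("the default LIF phantom matches the documented conditions", {
  ph <- generateLifPhantom(phantomConfig())
  cube <- phantomCube(ph)
  expect_equal(nBands(cube), 128L)
  expect_equal(spatialDims(cube), c(96L, 128L))
  expect_equal(range(wavelengths(cube)), c(380, 1050))
  expect_identical(scaleTag(cube), "dB")
  frac <- mean(phantomTruth(ph))
  expect_lt(abs(frac - 0.15), 0.2 * 0.15 + 1e-3)
})

test_that("phantom generation is deterministic given the seed", {
  p1 <- generateLifPhantom(phantomConfig(seed = 11L))
  p2 <- generateLifPhantom(phantomConfig(seed = 11L))
  expect_identical(cubeData(phantomCube(p1)), cubeData(phantomCube(p2)))
  expect_identical(phantomTruth(p1), phantomTruth(p2))
  p3 <- generateLifPhantom(phantomConfig(seed = 12L))
  expect_false(identical(phantomTruth(p1), phantomTruth(p3)))
})

test_that("phantom generation does not disturb the caller's RNG stream", {
  set.seed(77)
  before <- runif(1)
  set.seed(77)
  invisible(generateLifPhantom(phantomConfig(rows = 16L, cols = 16L,
                                             nBands = 16L)))
  expect_identical(runif(1), before)
})

test_that("a noiseless phantom equals the analytic emission model", {
  cfg <- phantomConfig(noiseSdDb = 0, rows = 24L, cols = 32L)
  ph <- generateLifPhantom(cfg)
  wl <- wavelengths(phantomCube(ph))
  shape <- exp(-(wl - 561)^2 / (2 * 25^2))
  tumor_px <- which(phantomTruth(ph), arr.ind = TRUE)[1, ]
  normal_px <- which(!phantomTruth(ph), arr.ind = TRUE)[1, ]
  expect_equal(cubeData(phantomCube(ph))[tumor_px[1], tumor_px[2], ],
               136 * shape, tolerance = 1e-12)
  expect_equal(cubeData(phantomCube(ph))[normal_px[1], normal_px[2], ],
               127 * shape, tolerance = 1e-12)
})

test_that("noiseless marker recovery hits the generator's emission center", {
  ph <- generateLifPhantom(phantomConfig(noiseSdDb = 0))
  mk <- selectMarkerBand(
    regionMeanSpectrum(phantomCube(ph), phantomTruth(ph)),
    regionMeanSpectrum(phantomCube(ph), !phantomTruth(ph)))
  spacing <- diff(wavelengths(phantomCube(ph)))[1]
  expect_lt(abs(lambdaPeak(mk) - 561), spacing / 2)
})

test_that("tumor amplitude is recovered within the noise tolerance", {
  ph <- generateLifPhantom(phantomConfig(seed = 1L))
  cube <- phantomCube(ph)
  truth <- phantomTruth(ph)
  wl <- wavelengths(cube)
  b <- which.min(abs(wl - 561))
  model_at_band <- 136 * exp(-(wl[b] - 561)^2 / (2 * 25^2))
  measured <- mean(cubeData(cube)[, , b][truth])
  expect_lt(abs(measured - model_at_band), 3 * 1 / sqrt(sum(truth)))
})

test_that("reflectance phantom calibrates to the designed absorption band", {
  ph <- generateReflectancePhantom(phantomConfig(seed = 5L))
  refl <- calibrateReflectance(phantomCube(ph), phantomRefs(ph))
  band <- detectAbsorptionBand(regionMeanSpectrum(refl, phantomTruth(ph)))
  spacing <- diff(wavelengths(phantomCube(ph)))[1]
  expect_lt(abs(lambdaLow(band) - 440), spacing)
  expect_lt(abs(lambdaHigh(band) - 460), spacing)
})

test_that("zero dip depth gives a no-band error", {
  ph <- generateReflectancePhantom(phantomConfig(noiseSdDb = 0, rows = 16L,
                                                 cols = 16L, nBands = 32L),
                                   dipDepthTumor = 0, dipDepthNormal = 0)
  refl <- calibrateReflectance(phantomCube(ph), phantomRefs(ph))
  expect_error(detectAbsorptionBand(regionMeanSpectrum(refl)),
               class = "hyperLIF_no_band_error")
})

test_that("calibration cancels the white-reference shading field exactly", {
  cfg <- phantomConfig(noiseSdDb = 0, rows = 16L, cols = 24L, nBands = 32L,
                       seed = 9L)
  ph <- generateReflectancePhantom(cfg)
  refl <- calibrateReflectance(phantomCube(ph), phantomRefs(ph))
  ## every tumor pixel carries the identical class reflectance spectrum even
  ## though the raw counts vary with the shading multiplier
  vals <- cubeData(refl)
  tumor_idx <- which(phantomTruth(ph))
  flat <- matrix(vals, prod(dim(vals)[1:2]), dim(vals)[3])[tumor_idx, ]
  expect_lt(max(apply(flat, 2, function(col) diff(range(col)))), 1e-9)
})

test_that("decay pair construction honors delay and the 1/e identity", {
  dp <- generateDecayPair(tauTumor = 3, tauNormal = 3, delay = 2,
                          dt = 0.5, n = 128)
  ## noiseless delta-pulse decay passes through 1/e at t = tau
  i_tau <- which.min(abs(dp$normal@t - 3))
  expect_equal(dp$normal@y[i_tau], exp(-1), tolerance = 1e-9)
  expect_equal(estimateTimeDelay(dp$tumor, dp$normal), 2, tolerance = 0.25)
  expect_error(generateDecayPair(-1, 2, dt = 0.5),
               class = "hyperLIF_contract_error")
  expect_error(generateDecayPair(1, 2, dt = 0.5, n = 4),
               class = "hyperLIF_contract_error")
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantomConfig(tumorFraction = 0.8))
  expect_error(phantomConfig(nBands = 4L))
  expect_error(phantomConfig(emissionCenter = 2000))
})
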