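test_that("region mean spectrum averages valid pixels band by band", {
  wl <- c(500, 550, 600)
  arr <- array(5, c(2, 2, 3))
  cube <- HSCube(arr, wl)
  sig <- regionMeanSpectrum(cube, matrix(TRUE, 2, 2))
  expect_equal(signatureValues(sig), rep(5, 3))
  expect_equal(nPixels(sig), 4L)
  ## two pixels holding 2 and 4 average to 3
  arr2 <- array(NA_real_, c(1, 2, 3))
  arr2[1, 1, ] <- 2; arr2[1, 2, ] <- 4
  sig2 <- regionMeanSpectrum(HSCube(arr2, wl), matrix(TRUE, 1, 2))
  expect_equal(signatureValues(sig2), rep(3, 3))
  ## masks selecting nothing valid are a contract error
  arr3 <- array(NA_real_, c(2, 2, 3))
  arr3[2, , ] <- 1
  cube3 <- HSCube(arr3, wl)
  bad_mask <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)  # row 1 only
  expect_error(regionMeanSpectrum(cube3, bad_mask),
               class = "hyperLIF_contract_error")
  expect_error(regionMeanSpectrum(cube3, matrix(FALSE, 2, 2)),
               class = "hyperLIF_contract_error")
})

test_that("signatures over disjoint regions pool by pixel-count weighting", {
  cube <- tinyCube(6, 8, 5, seed = 21)
  m1 <- matrix(FALSE, 6, 8); m1[1:2, ] <- TRUE
  m2 <- matrix(FALSE, 6, 8); m2[5:6, 3:8] <- TRUE
  s1 <- regionMeanSpectrum(cube, m1)
  s2 <- regionMeanSpectrum(cube, m2)
  s12 <- regionMeanSpectrum(cube, m1 | m2)
  pooled <- (nPixels(s1) * signatureValues(s1) +
             nPixels(s2) * signatureValues(s2)) /
    (nPixels(s1) + nPixels(s2))
  expect_equal(signatureValues(s12), pooled, tolerance = 1e-9)
})

test_that("band statistics give the histogram, mean and population SD", {
  bs <- bandStatistics(matrix(c(0, 255), 1, 2), nBins = 2)
  expect_equal(bs$mean, 127.5)
  expect_equal(bs$sd, 127.5)  # population SD, not the n-1 sample SD
  expect_equal(sum(bs$counts), 2)
  const <- bandStatistics(matrix(7, 3, 3))
  expect_equal(const$mean, 7)
  expect_equal(const$sd, 0)
  expect_equal(const$counts, 9)
  expect_error(bandStatistics(matrix(NA_real_, 2, 2)),
               class = "hyperLIF_contract_error")
})

test_that("absorption-band detection recovers the half-depth interval", {
  ## analytic dip centered 450 nm with half-depth half-width 10 nm on a dense
  ## grid; dense-scan oracle confirms the analytic center before asserting
  wl <- seq(380, 700, by = 0.5)
  sigma <- 10 / sqrt(2 * log(2))
  absorb <- function(x) 0.10 + 0.30 * exp(-(x - 450)^2 / (2 * sigma^2))
  expect_equal(denseArgmax(absorb, 380, 700), 450, tolerance = 0.02)
  sig <- spectralSignature(wl, absorb(wl), scaleTag = "absorbance",
                           nPixels = 10L)
  band <- detectAbsorptionBand(sig, depthFraction = 0.5)
  expect_equal(lambdaLow(band), 440, tolerance = 0.3)
  expect_equal(lambdaHigh(band), 460, tolerance = 0.3)
  ## same shape shifted to 600 nm detects a band centered there, not at 450
  sig6 <- spectralSignature(wl, 0.10 + 0.30 *
                              exp(-(wl - 600)^2 / (2 * sigma^2)),
                            scaleTag = "absorbance", nPixels = 10L)
  band6 <- detectAbsorptionBand(sig6, 0.5)
  expect_equal((lambdaLow(band6) + lambdaHigh(band6)) / 2, 600,
               tolerance = 0.3)
})

test_that("flat signatures raise a no-band error", {
  wl <- seq(400, 700, by = 5)
  sig <- spectralSignature(wl, rep(0.2, length(wl)),
                           scaleTag = "absorbance", nPixels = 4L)
  expect_error(detectAbsorptionBand(sig), class = "hyperLIF_no_band_error")
})

test_that("band detection is invariant to adding a constant", {
  wl <- seq(380, 700, by = 2)
  sigma <- 10 / sqrt(2 * log(2))
  vals <- 0.1 + 0.25 * exp(-(wl - 450)^2 / (2 * sigma^2))
  b1 <- detectAbsorptionBand(spectralSignature(wl, vals, "absorbance", 5L))
  b2 <- detectAbsorptionBand(spectralSignature(wl, vals + 3.2,
                                               "absorbance", 5L))
  expect_equal(lambdaLow(b1), lambdaLow(b2), tolerance = 1e-9)
  expect_equal(lambdaHigh(b1), lambdaHigh(b2), tolerance = 1e-9)
})

test_that("reflectance signatures are converted to absorbance internally", {
  wl <- seq(380, 700, by = 1)
  sigma <- 10 / sqrt(2 * log(2))
  refl <- 0.8 * 10^(-0.3 * exp(-(wl - 450)^2 / (2 * sigma^2)))
  band <- detectAbsorptionBand(
    spectralSignature(wl, refl, "reflectance", 5L), 0.5)
  expect_equal(lambdaLow(band), 440, tolerance = 0.6)
  expect_equal(lambdaHigh(band), 460, tolerance = 0.6)
})

test_that("excitation wavelength is the band midpoint", {
  expect_equal(excitationCenter(absorptionBand(440, 460)), 450)
  expect_equal(excitationCenter(absorptionBand(500, 520)), 510)
  expect_error(absorptionBand(450, 450))
})

test_that("marker selection locates the maximal-difference wavelength", {
  ## Gaussian tumor-normal difference centered exactly at 561 nm on the
  ## 128-band 380-1050 nm grid; dense-scan oracle confirms the analytic peak
  wl <- seq(380, 1050, length.out = 128)
  diff_fun <- function(x) 9 * exp(-(x - 561)^2 / (2 * 25^2))
  expect_equal(denseArgmax(diff_fun, 380, 1050), 561, tolerance = 0.02)
  normal <- spectralSignature(wl, rep(127, 128), "dB", 100L)
  tumor <- spectralSignature(wl, 127 + diff_fun(wl), "dB", 100L)
  mk <- selectMarkerBand(tumor, normal)
  expect_equal(lambdaPeak(mk), 561, tolerance = 0.5)
  expect_gt(markerDelta(mk), 0)
})

test_that("a difference peaking exactly at a band center is not displaced", {
  wl <- seq(400, 700, by = 5)
  diff_vals <- 4 * exp(-(wl - 550)^2 / (2 * 30^2))  # 550 is a grid point
  normal <- spectralSignature(wl, rep(1, length(wl)), "dB", 10L)
  tumor <- spectralSignature(wl, 1 + diff_vals, "dB", 10L)
  mk <- selectMarkerBand(tumor, normal)
  expect_equal(lambdaPeak(mk), 550, tolerance = 1e-9)
  expect_equal(markerDelta(mk), 4, tolerance = 1e-9)
})

test_that("marker selection is antisymmetric in its arguments", {
  wl <- seq(380, 1050, length.out = 128)
  set.seed(5)
  normal <- spectralSignature(wl, 127 + rnorm(128, sd = 0.05), "dB", 50L)
  tumor <- spectralSignature(wl,
                             signatureValues(normal) +
                               9 * exp(-(wl - 561)^2 / (2 * 25^2)),
                             "dB", 50L)
  m1 <- selectMarkerBand(tumor, normal)
  m2 <- selectMarkerBand(normal, tumor)
  expect_equal(lambdaPeak(m1), lambdaPeak(m2))
  expect_equal(markerDelta(m1), -markerDelta(m2))
})

test_that("identical signatures raise a no-marker error", {
  wl <- c(500, 550, 600)
  s <- spectralSignature(wl, c(1, 2, 3), "dB", 5L)
  expect_error(selectMarkerBand(s, s), class = "hyperLIF_no_marker_error")
  ## fewer than 3 bands is a precondition failure
  s2 <- spectralSignature(c(500, 550), c(1, 2), "dB", 5L)
  expect_error(selectMarkerBand(s2, s2), class = "hyperLIF_contract_error")
})

test_that("signature CSV export round-trips", {
  sig <- spectralSignature(c(500, 550, 600), c(1.5, 2.5, 3.5), "dB", 12L)
  p <- file.path(tempdir(), "sig.csv")
  writeSignatureCSV(sig, p)
  back <- readSignatureCSV(p, scaleTag = "dB", nPixels = 12L)
  expect_equal(signatureValues(back), signatureValues(sig))
  expect_equal(wavelengths(back), wavelengths(sig))
})
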