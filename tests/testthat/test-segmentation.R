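test_that("8-bit normalization maps endpoints and rounds ties away from zero", {
  img <- matrix(c(0, 0.5, 1), 1)
  expect_equal(normalize8bit(img), matrix(c(0, 128, 255), 1))
  set.seed(9)
  r <- matrix(runif(30, -5, 17), 5, 6)
  n <- normalize8bit(r)
  expect_equal(n[which.min(r)], 0)
  expect_equal(n[which.max(r)], 255)
  expect_true(all(n >= 0 & n <= 255 & n == round(n)))
  ## constant image maps to all zeros; all-invalid is a contract error
  expect_true(all(normalize8bit(matrix(4.2, 3, 3)) == 0))
  expect_error(normalize8bit(matrix(NA_real_, 2, 2)),
               class = "hyperLIF_contract_error")
  ## invalid pixels stay NA and do not influence the range
  img2 <- matrix(c(0, 1, NA, 2), 2, 2)
  n2 <- normalize8bit(img2)
  expect_true(is.na(n2[1, 2]))
  expect_equal(n2[2, 2], 255)
})

test_that("K-means matches the brute-force optimum on the four-point fixture", {
  oracle <- bruteForceKmeans2(c(0, 1, 8, 9))
  expect_equal(oracle$objective, 1)          # frozen: {0,1} and {8,9}
  expect_equal(oracle$centroids, c(0.5, 8.5))
  m <- kmeansFit(c(0, 1, 8, 9), kmeansConfig(k = 2))
  expect_equal(sort(centroids(m)[, 1]), c(0.5, 8.5))
  expect_equal(objectiveValue(m), 1)
})

test_that("K-means degenerate cases: k = 1 and k = n", {
  x <- c(2, 4, 6, 11)
  m1 <- kmeansFit(x, kmeansConfig(k = 1))
  expect_equal(centroids(m1)[1, 1], mean(x))
  expect_equal(objectiveValue(m1), sum((x - mean(x))^2))
  mn <- kmeansFit(x, kmeansConfig(k = 4))
  expect_equal(objectiveValue(mn), 0)
  expect_error(kmeansFit(c(1, 2), kmeansConfig(k = 3)),
               class = "hyperLIF_contract_error")
})

test_that("K-means objective is non-increasing and self-consistent", {
  set.seed(101)
  for (rep in 1:5) {
    pts <- cbind(rnorm(60, sample(c(0, 5, 9), 60, TRUE)), rnorm(60))
    m <- kmeansFit(pts, kmeansConfig(k = 4))
    trace <- objectiveTrace(m)
    expect_true(all(diff(trace) <= 1e-9))
    recomputed <- sum((pts - centroids(m)[clusterLabels(m), ])^2)
    expect_equal(recomputed, objectiveValue(m), tolerance = 1e-9)
  }
})

test_that("farthest-point K-means attains the enumerated optimum on small instances", {
  ## scalar instances with separated modes, mimicking the multimodal band
  ## intensities the pipeline actually clusters; oracle enumerates contiguous
  ## partitions of the sorted points
  set.seed(2024)
  n_opt <- 0L
  n_total <- 100L
  for (i in seq_len(n_total)) {
    k <- sample(2:3, 1)
    n <- sample((k + 2):12, 1)
    x <- rnorm(n, sample(c(0, 4, 10), n, TRUE), 0.5)
    opt <- bruteForceKmeans1d(x, k)
    m <- kmeansFit(x, kmeansConfig(k = k))
    recomputed <- sum((x - centroids(m)[clusterLabels(m), 1])^2)
    expect_equal(recomputed, objectiveValue(m), tolerance = 1e-9)
    expect_gte(objectiveValue(m), opt - 1e-9)
    if (objectiveValue(m) <= opt + 1e-6) n_opt <- n_opt + 1L
  }
  expect_gte(n_opt, 95L)
})

test_that("random initialization is deterministic given the seed", {
  x <- rnorm(40)
  m1 <- kmeansFit(x, kmeansConfig(k = 3, init = "random", seed = 7))
  m2 <- kmeansFit(x, kmeansConfig(k = 3, init = "random", seed = 7))
  expect_identical(clusterLabels(m1), clusterLabels(m2))
  expect_equal(centroids(m1), centroids(m2))
})

test_that("malignant labeling thresholds centroids inclusively", {
  model <- new("ClusterModel",
               centroids = matrix(c(0.3, 1.8, 0.9), 3, 1),
               labels = c(1L, 2L, 3L, 2L),
               objective = 0, nIter = 1L, objectiveTrace = 0)
  expect_equal(labelMalignantClusters(model, 1.7),
               c(FALSE, TRUE, FALSE, TRUE))
  ## centroid exactly at the threshold is included (>= semantics)
  model2 <- new("ClusterModel", centroids = matrix(c(1.7, 1.0), 2, 1),
                labels = c(1L, 2L), objective = 0, nIter = 1L,
                objectiveTrace = 0)
  expect_equal(labelMalignantClusters(model2, 1.7), c(TRUE, FALSE))
  ## all centroids below the threshold yields an empty map
  expect_false(any(labelMalignantClusters(model, 5)))
})

test_that("malignant labeling is monotone in the threshold", {
  set.seed(12)
  model <- kmeansFit(runif(200, 0, 2.55), kmeansConfig(k = 8))
  prev <- rep(TRUE, 200)
  for (thr in seq(0, 3, by = 0.25)) {
    cur <- labelMalignantClusters(model, thr)
    expect_true(all(cur <= prev))  # raising the threshold never adds pixels
    prev <- cur
  }
})

test_that("contours close around mask components", {
  expect_identical(extractContours(matrix(FALSE, 4, 4)), list())
  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  cs <- extractContours(single)
  expect_length(cs, 1)
  expect_equal(cs[[1]][1, ], cs[[1]][nrow(cs[[1]]), ])
  two <- matrix(FALSE, 9, 9)
  two[2:3, 2:3] <- TRUE
  two[6:8, 6:8] <- TRUE
  expect_length(extractContours(two), 2)
  ## blobs touching the image edge still produce closed loops
  edge <- matrix(FALSE, 4, 4); edge[1:2, 1:2] <- TRUE
  ce <- extractContours(edge)
  expect_length(ce, 1)
  expect_equal(ce[[1]][1, ], ce[[1]][nrow(ce[[1]]), ])
})

test_that("filling extracted contours recovers simply-connected blobs", {
  mask <- matrix(FALSE, 10, 12)
  mask[3:6, 4:9] <- TRUE
  mask[5:8, 8:11] <- TRUE   # union is one simply-connected blob
  cs <- extractContours(mask)
  expect_length(cs, 1)
  expect_identical(fillContours(cs, dim(mask)), mask)
})

test_that("segmentation recovers a noiseless two-level image exactly", {
  truth <- matrix(FALSE, 12, 14)
  truth[4:8, 5:10] <- TRUE
  img <- matrix(100, 12, 14)
  img[truth] <- 200
  dm <- segmentMarkerImage(img, kmeansConfig(k = 2), threshold = 1.7)
  expect_identical(malignantMask(dm), truth)
  expect_length(maskContours(dm), 1)
  expect_equal(thresholdUsed(dm), 1.7)
})

test_that("an all-background image yields an empty mask and no contours", {
  img <- matrix(5, 8, 8)
  dm <- segmentMarkerImage(img, kmeansConfig(k = 1), threshold = 1.7)
  expect_false(any(malignantMask(dm)))
  expect_length(maskContours(dm), 0)
})

test_that("default phantom segmentation agrees with ground truth", {
  ph <- generateLifPhantom(phantomConfig(seed = 42L))
  cube <- phantomCube(ph)
  sigs_t <- regionMeanSpectrum(cube, phantomTruth(ph))
  sigs_n <- regionMeanSpectrum(cube, !phantomTruth(ph))
  mk <- selectMarkerBand(sigs_t, sigs_n)
  dm <- segmentMarkerImage(cubeData(cube)[, , bandIndex(mk)])
  agreement <- mean(malignantMask(dm) == phantomTruth(ph))
  expect_gte(agreement, 0.94)
})

test_that("mask and contour exports round-trip", {
  mask <- matrix(FALSE, 6, 7)
  mask[2:4, 3:5] <- TRUE
  p1 <- file.path(tempdir(), "mask.png")
  writeMaskPNG(mask, p1)
  expect_identical(readMaskPNG(p1), mask)
  p2 <- file.path(tempdir(), "mask.tsv")
  writeMaskRunLength(mask, p2)
  expect_identical(readMaskRunLength(p2, dim(mask)), mask)
  p3 <- file.path(tempdir(), "contours.json")
  writeContoursJSON(extractContours(mask), p3)
  gj <- jsonlite::read_json(p3)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 1)
})
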