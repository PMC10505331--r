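## Independent oracles used across test files. These deliberately avoid the
## package's own code paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Brute-force k-means optimum by enumerating every labeling (small n, k = 2).
bruteForceKmeans2 <- function(points) {
  pts <- matrix(points, ncol = 1)
  n <- nrow(pts)
  best <- Inf
  best_ctr <- NULL
  for (code in 1:(2^n - 2)) {
    lab <- as.integer(intToBits(code))[1:n] + 1L
    if (length(unique(lab)) < 2L) next
    ctr <- rbind(colMeans(pts[lab == 1L, , drop = FALSE]),
                 colMeans(pts[lab == 2L, , drop = FALSE]))
    sse <- sum((pts - ctr[lab, , drop = FALSE])^2)
    if (sse < best) {
      best <- sse
      best_ctr <- ctr
    }
  }
  list(objective = best, centroids = sort(best_ctr[, 1]))
}

## Optimal 1-D k-means by enumerating contiguous partitions of the sorted
## points (optimal 1-D partitions are contiguous in sorted order).
bruteForceKmeans1d <- function(points, k) {
  x <- sort(points)
  n <- length(x)
  splits <- utils::combn(n - 1L, k - 1L)
  best <- Inf
  for (j in seq_len(ncol(splits))) {
    bounds <- c(0L, splits[, j], n)
    sse <- 0
    for (g in seq_len(k)) {
      seg <- x[(bounds[g] + 1L):bounds[g + 1L]]
      sse <- sse + sum((seg - mean(seg))^2)
    }
    if (sse < best) best <- sse
  }
  best
}

## Even-odd point-in-polygon test for filling closed contours back to a mask.
pointInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n - 1L  # poly is closed: last vertex repeats the first
  for (i in seq_len(n - 1L)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

fillContours <- function(contours, dims) {
  mask <- matrix(FALSE, dims[1], dims[2])
  for (r in seq_len(dims[1]))
    for (cc in seq_len(dims[2]))
      for (poly in contours)
        if (pointInPolygon(r, cc, poly)) {
          mask[r, cc] <- TRUE
          break
        }
  mask
}

## Dense-grid scan oracle for peak/band location of an analytic curve.
denseArgmax <- function(f, lo, hi, step = 0.01) {
  xs <- seq(lo, hi, by = step)
  xs[which.max(f(xs))]
}

tinyCube <- function(rows = 2, cols = 3, bands = 4, wl = NULL,
                     scaleTag = "raw_counts", seed = 7) {
  if (is.null(wl)) wl <- seq(400, 700, length.out = bands)
  set.seed(seed)
  HSCube(array(round(runif(rows * cols * bands) * 100),
               c(rows, cols, bands)), wl, scaleTag)
}
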