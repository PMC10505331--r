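#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' 8-bit min-max normalization of a band image
#'
#' Linearly maps valid pixels onto [0, 255] and rounds to the nearest integer
#' with ties away from zero (so 127.5 becomes 128). A constant image maps to
#' all zeros. Invalid pixels stay \code{NA}.
#'
#' @param image 2-D numeric matrix.
#' @return Integer-valued matrix in [0, 255].
#' @examples
#' normalize8bit(matrix(c(0, 0.5, 1), 1))  # 0 128 255
#' @export
normalize8bit <- function(image) {
  stopifnot(is.matrix(image))
  v <- image
  ok <- is.finite(v)
  if (!any(ok)) .contract_error("image has no valid pixels")
  lo <- min(v[ok]); hi <- max(v[ok])
  out <- matrix(NA_real_, nrow(v), ncol(v))
  if (hi > lo) {
    out[ok] <- .round_half_away((v[ok] - lo) / (hi - lo) * 255)
  } else {
    out[ok] <- 0
  }
  out
}

.pairwise_sqdist <- function(pts, ctr) {
  ## n x k matrix of squared Euclidean distances
  n2p <- rowSums(pts^2)
  n2c <- rowSums(ctr^2)
  outer(n2p, n2c, "+") - 2 * pts %*% t(ctr)
}

.kmeans_objective <- function(pts, ctr, labels) {
  sum((pts - ctr[labels, , drop = FALSE])^2)
}

.farthest_point_init <- function(pts, k) {
  ## first center: the point nearest the data mean (centers "placed as widely
  ## apart as feasible" is then achieved greedily by max-min distance)
  ctr_idx <- integer(k)
  mu <- colMeans(pts)
  d0 <- rowSums(sweep(pts, 2, mu)^2)
  ctr_idx[1] <- which.min(d0)
  if (k > 1L) {
    mind <- rowSums(sweep(pts, 2, pts[ctr_idx[1], ])^2)
    for (j in 2:k) {
      ctr_idx[j] <- which.max(mind)
      if (j < k) {
        dj <- rowSums(sweep(pts, 2, pts[ctr_idx[j], ])^2)
        mind <- pmin(mind, dj)
      }
    }
  }
  pts[ctr_idx, , drop = FALSE]
}

#' Lloyd K-means clustering
#'
#' From-scratch Lloyd iterations minimizing the within-cluster sum of squared
#' Euclidean distances \eqn{J(V) = \sum_j \sum_{i \in C_j} \|z_i - ce_j\|^2}:
#' each point is assigned to its nearest centroid (ties to the lowest cluster
#' index), then each centroid is recomputed as the mean of its members, until
#' the maximal centroid shift drops below \code{tol} or \code{maxIter} is
#' reached. The default deterministic \code{farthest_point} initialization
#' places the first center at the point nearest the data mean and each
#' subsequent center at the point maximizing the minimal distance to those
#' already chosen; \code{init = "random"} samples k distinct points using the
#' config seed. A cluster emptied during iteration is re-seeded with the point
#' currently farthest from its centroid. The per-iteration objective trace is
#' recorded and is non-increasing.
#'
#' @param points numeric vector (1-D features) or n x d matrix.
#' @param config a \linkS4class{KMeansConfig}.
#' @return A \linkS4class{ClusterModel}.
#' @examples
#' m <- kmeansFit(c(0, 1, 8, 9), kmeansConfig(k = 2))
#' centroids(m)       # 0.5 and 8.5
#' objectiveValue(m)  # 1
#' @export
kmeansFit <- function(points, config = kmeansConfig()) {
  stopifnot(is(config, "KMeansConfig"))
  validObject(config)
  pts <- if (is.matrix(points)) points else matrix(points, ncol = 1L)
  storage.mode(pts) <- "double"
  if (anyNA(pts)) .contract_error("points must not contain NA")
  n <- nrow(pts)
  k <- config@k
  if (n < k) .contract_error(sprintf("need at least k = %d points, got %d", k, n))
  ctr <- if (config@init == "farthest_point") {
    .farthest_point_init(pts, k)
  } else {
    .with_seed(config@seed, pts[sample.int(n, k), , drop = FALSE])
  }
  labels <- integer(n)
  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- .pairwise_sqdist(pts, ctr)
    labels <- max.col(-d2, ties.method = "first")
    ## refill empty clusters with the point farthest from its centroid
    repeat {
      empty <- setdiff(seq_len(k), unique(labels))
      if (!length(empty)) break
      j <- empty[1]
      cur <- rowSums((pts - ctr[labels, , drop = FALSE])^2)
      far <- which.max(cur)
      ctr[j, ] <- pts[far, ]
      labels[far] <- j
    }
    new_ctr <- ctr
    for (j in seq_len(k)) {
      members <- labels == j
      new_ctr[j, ] <- colMeans(pts[members, , drop = FALSE])
    }
    shift <- sqrt(max(rowSums((new_ctr - ctr)^2)))
    ctr <- new_ctr
    trace <- c(trace, .kmeans_objective(pts, ctr, labels))
    if (shift < config@tol || iter >= config@maxIter) break
  }
  new("ClusterModel", centroids = ctr, labels = labels,
      objective = .kmeans_objective(pts, ctr, labels),
      nIter = iter, objectiveTrace = trace)
}

#' Label malignant clusters by centroid threshold
#'
#' A cluster is malignant iff its (scalar) centroid is greater than or equal
#' to the threshold — the inclusive boundary matches the published
#' \dQuote{threshold value >= 1.7} rule. The threshold lives on the
#' pre-processed intensity scale: after 8-bit normalization the image is
#' rescaled by 0.01 to [0, 2.55] before clustering (see
#' \code{\link{segmentMarkerImage}}), making 1.7 a high-intensity cutoff at
#' two thirds of the dynamic range.
#'
#' @param model a \linkS4class{ClusterModel} fitted on scalar intensities.
#' @param threshold centroid cutoff (default 1.7).
#' @return Logical vector, one entry per clustered point.
#' @export
labelMalignantClusters <- function(model, threshold = 1.7) {
  stopifnot(is(model, "ClusterModel"))
  if (ncol(model@centroids) != 1L)
    .contract_error("threshold labeling expects a model fitted on scalar intensities")
  malignant <- model@centroids[, 1] >= threshold
  malignant[model@labels]
}

#' Extract closed boundary contours of a binary mask
#'
#' Marching-squares boundaries at level 0.5 of the binary map (computed on a
#' zero-padded copy so blobs touching the image edge still close). One closed
#' polyline per connected boundary component, in (row, col) pixel
#' coordinates.
#'
#' @param mask logical or 0/1 matrix.
#' @return List of 2-column (row, col) matrices; each polyline's first and
#'   last vertices coincide.
#' @export
extractContours <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  m[is.na(m)] <- 0
  if (!any(m > 0)) return(list())
  nr <- nrow(m); nc <- ncol(m)
  padded <- matrix(0, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- m
  cl <- grDevices::contourLines(x = 0:(nr + 1L), y = 0:(nc + 1L),
                                z = padded, levels = 0.5)
  lapply(cl, function(cc) {
    out <- cbind(row = cc$x, col = cc$y)
    ## ensure closure (contourLines closes interior loops; guard regardless)
    if (!isTRUE(all.equal(out[1, ], out[nrow(out), ])))
      out <- rbind(out, out[1, ])
    out
  })
}

#' Segment a marker-band image and delineate malignant regions
#'
#' The full single-band delineation chain: 8-bit normalization, rescaling by
#' \code{rescaleFactor} onto the clustering scale, K-means clustering of the
#' scalar intensities (K = 8 by default), malignant labeling of clusters with
#' centroid >= \code{threshold}, and contour extraction around the resulting
#' mask.
#'
#' @param image 2-D band image (e.g. the 561 nm emission band).
#' @param config a \linkS4class{KMeansConfig}.
#' @param threshold centroid cutoff on the rescaled intensity scale
#'   (default 1.7).
#' @param rescaleFactor scale applied after 8-bit normalization (default
#'   0.01, mapping [0, 255] to [0, 2.55]).
#' @return A \linkS4class{DelineationMask}.
#' @export
segmentMarkerImage <- function(image, config = kmeansConfig(),
                               threshold = 1.7, rescaleFactor = 0.01) {
  norm <- normalize8bit(image)
  scaled <- norm * rescaleFactor
  ok <- is.finite(scaled)
  pts <- scaled[ok]
  model <- kmeansFit(pts, config)
  flags <- labelMalignantClusters(model, threshold)
  mask <- matrix(FALSE, nrow(image), ncol(image))
  mask[ok] <- flags
  new("DelineationMask", malignant = mask,
      contours = extractContours(mask),
      threshold = as.numeric(threshold))
}

#' Write a binary mask as PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeMaskPNG <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read a binary mask from PNG
#'
#' @param path PNG path; any channel value > 0.5 counts as TRUE.
#' @return Logical matrix.
#' @export
readMaskPNG <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

#' Write a mask as run-length text
#'
#' One line per horizontal run of TRUE pixels: \code{row col_start col_end}
#' (1-based, inclusive), tab-separated with a header.
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMaskRunLength <- function(mask, path) {
  runs <- list()
  for (r in seq_len(nrow(mask))) {
    rl <- rle(as.vector(mask[r, ]))
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    w <- which(rl$values)
    if (length(w))
      runs[[length(runs) + 1L]] <-
        data.frame(row = r, col_start = starts[w], col_end = ends[w])
  }
  df <- if (length(runs)) do.call(rbind, runs)
        else data.frame(row = integer(), col_start = integer(),
                        col_end = integer())
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run-length text mask
#'
#' @param path file written by \code{\link{writeMaskRunLength}}.
#' @param dims integer(2) spatial dimensions of the mask.
#' @return Logical matrix.
#' @export
readMaskRunLength <- function(path, dims) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  mask <- matrix(FALSE, dims[1], dims[2])
  for (i in seq_len(nrow(df)))
    mask[df$row[i], df$col_start[i]:df$col_end[i]] <- TRUE
  mask
}

#' Write contours as GeoJSON-style JSON
#'
#' @param contours list of closed (row, col) polylines.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeContoursJSON <- function(contours, path) {
  features <- lapply(contours, function(cc) {
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(cc)),
                           function(i) as.numeric(cc[i, ])))),
         properties = list())
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
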