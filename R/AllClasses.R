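#' @import methods
NULL

.SCALE_TAGS <- c("raw_counts", "reflectance", "normalized8", "dB", "absorbance")

## Invalid pixels are carried as NA (the reserved sentinel); every statistic in
## the package excludes them. Extra per-pixel flags (e.g. specular glints with
## reflectance > 1.05) live in metadata as logical matrices.

#' HSCube: a hyperspectral image cube
#'
#' Central data object of the package: a rows x cols x bands array of
#' intensities together with its spectral axis (band-center wavelengths in nm)
#' and a scale tag recording the physical scale of the values. Invalid pixels
#' are stored as \code{NA} and excluded from all downstream statistics.
#'
#' @slot data 3-D numeric array, spatial rows x cols with the band axis last.
#' @slot wavelength numeric vector of band-center wavelengths (nm), strictly
#'   increasing, one per band.
#' @slot scaleTag one of \code{"raw_counts"}, \code{"reflectance"},
#'   \code{"normalized8"}, \code{"dB"}, \code{"absorbance"}.
#' @slot metadata list of free-form annotations (e.g. \code{glintMask}, a
#'   logical matrix flagging reflectance > 1.05).
#'
#' @export
setClass("HSCube",
  representation(
    data = "array",
    wavelength = "numeric",
    scaleTag = "character",
    metadata = "list"
  )
)

setValidity("HSCube", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L)
    return("data must be a 3-D array (rows x cols x bands)")
  if (any(d[1:2] < 1L))
    return("cube must have at least one row and one column")
  if (d[3] != length(object@wavelength))
    return(sprintf("bands dimension (%d) must equal wavelength length (%d)",
                   d[3], length(object@wavelength)))
  wl <- object@wavelength
  if (length(wl) < 1L) return("wavelength grid must be non-empty")
  if (any(!is.finite(wl)) || any(wl <= 0) || any(wl >= 20000))
    return("wavelengths must be finite and in (0, 20000) nm")
  if (length(wl) > 1L && any(diff(wl) <= 0))
    return("wavelengths must be strictly increasing")
  if (length(object@scaleTag) != 1L || !(object@scaleTag %in% .SCALE_TAGS))
    return(paste("scaleTag must be one of:", paste(.SCALE_TAGS, collapse = ", ")))
  v <- object@data[!is.na(object@data)]
  if (object@scaleTag == "reflectance" && length(v) && any(v < 0))
    return("reflectance values must be >= 0 (invalid pixels are NA)")
  if (object@scaleTag == "normalized8" && length(v) &&
      (any(v < 0) || any(v > 255)))
    return("normalized8 values must lie in [0, 255]")
  TRUE
})

#' Construct an HSCube
#'
#' @param data rows x cols x bands numeric array.
#' @param wavelength band-center wavelengths in nm, strictly increasing.
#' @param scaleTag physical scale of the values (default \code{"raw_counts"}).
#' @param metadata optional list of annotations.
#' @return An \linkS4class{HSCube}.
#' @examples
#' cube <- HSCube(array(1:24, c(2, 3, 4)), wavelength = c(450, 500, 550, 600))
#' nBands(cube)
#' @export
HSCube <- function(data, wavelength, scaleTag = "raw_counts",
                   metadata = list()) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  storage.mode(data) <- "double"
  new("HSCube", data = data, wavelength = as.numeric(wavelength),
      scaleTag = scaleTag, metadata = metadata)
}

#' ReferenceFrames: white and dark calibration references
#'
#' Holds the dark (shutter closed) and white (high-reflectivity standard)
#' reference frames used by \code{\link{calibrateReflectance}}. Either 2-D
#' (spatial, shared across bands) or 3-D matching the cube shape.
#'
#' @slot dark numeric matrix or array.
#' @slot white numeric matrix or array of the same shape as \code{dark}.
#' @export
setClass("ReferenceFrames",
  representation(dark = "array", white = "array")
)

setValidity("ReferenceFrames", function(object) {
  if (!identical(dim(object@dark), dim(object@white)))
    return("dark and white references must have identical shapes")
  nd <- length(dim(object@dark))
  if (!(nd %in% c(2L, 3L)))
    return("references must be 2-D (spatial) or 3-D (per-band)")
  TRUE
})

#' Construct ReferenceFrames
#'
#' @param dark,white numeric matrices or 3-D arrays of identical shape.
#' @return A \linkS4class{ReferenceFrames}.
#' @export
referenceFrames <- function(dark, white) {
  dark <- .as_ref_array(dark)
  white <- .as_ref_array(white)
  new("ReferenceFrames", dark = dark, white = white)
}

.as_ref_array <- function(x) {
  if (is.matrix(x)) x <- array(x, dim(x))
  storage.mode(x) <- "double"
  x
}

#' SpectralSignature: per-band mean intensity of a region
#'
#' @slot wavelength band-center wavelengths (nm).
#' @slot values per-band mean intensity over the contributing pixels.
#' @slot scaleTag physical scale of the values.
#' @slot nPixels number of valid pixels contributing to the means.
#' @export
setClass("SpectralSignature",
  representation(
    wavelength = "numeric",
    values = "numeric",
    scaleTag = "character",
    nPixels = "integer"
  )
)

setValidity("SpectralSignature", function(object) {
  if (length(object@values) != length(object@wavelength))
    return("values and wavelength must have equal length")
  if (length(object@nPixels) != 1L || is.na(object@nPixels) ||
      object@nPixels < 1L)
    return("nPixels must be a single count >= 1")
  if (!(object@scaleTag %in% .SCALE_TAGS))
    return(paste("scaleTag must be one of:", paste(.SCALE_TAGS, collapse = ", ")))
  TRUE
})

#' Construct a SpectralSignature
#' @param wavelength band-center wavelengths (nm).
#' @param values per-band intensities.
#' @param scaleTag physical scale of the values.
#' @param nPixels number of pixels the signature averages over.
#' @return A \linkS4class{SpectralSignature}.
#' @export
spectralSignature <- function(wavelength, values, scaleTag = "raw_counts",
                              nPixels = 1L) {
  new("SpectralSignature", wavelength = as.numeric(wavelength),
      values = as.numeric(values), scaleTag = scaleTag,
      nPixels = as.integer(nPixels))
}

#' AbsorptionBand: a contiguous wavelength interval of strong absorption
#'
#' @slot lambdaLow,lambdaHigh interval endpoints in nm, low < high.
#' @export
setClass("AbsorptionBand",
  representation(lambdaLow = "numeric", lambdaHigh = "numeric")
)

setValidity("AbsorptionBand", function(object) {
  if (length(object@lambdaLow) != 1L || length(object@lambdaHigh) != 1L)
    return("band endpoints must be scalars")
  if (!is.finite(object@lambdaLow) || !is.finite(object@lambdaHigh) ||
      object@lambdaLow >= object@lambdaHigh)
    return("band requires finite lambdaLow < lambdaHigh")
  TRUE
})

#' Construct an AbsorptionBand
#' @param lambdaLow,lambdaHigh interval endpoints (nm), low < high.
#' @return An \linkS4class{AbsorptionBand}.
#' @export
absorptionBand <- function(lambdaLow, lambdaHigh) {
  new("AbsorptionBand", lambdaLow = as.numeric(lambdaLow),
      lambdaHigh = as.numeric(lambdaHigh))
}

#' MarkerBand: emission band of maximal tumor-normal separation
#'
#' @slot bandIndex index of the band with maximal absolute tumor-normal
#'   difference (1-based).
#' @slot lambdaPeak peak wavelength (nm) refined by 3-point parabolic
#'   interpolation, not quantized to the band grid.
#' @slot delta interpolated tumor minus normal difference at the peak, in
#'   signature units.
#' @export
setClass("MarkerBand",
  representation(bandIndex = "integer", lambdaPeak = "numeric",
                 delta = "numeric")
)

#' KMeansConfig: settings for the Lloyd clustering stage
#'
#' @slot k number of clusters (default 8, the value used throughout the
#'   delineation workflow).
#' @slot maxIter iteration cap.
#' @slot tol centroid-shift convergence threshold.
#' @slot seed RNG seed, used only for \code{init = "random"}.
#' @slot init \code{"farthest_point"} (deterministic, default) or
#'   \code{"random"}.
#' @export
setClass("KMeansConfig",
  representation(k = "integer", maxIter = "integer", tol = "numeric",
                 seed = "integer", init = "character")
)

setValidity("KMeansConfig", function(object) {
  if (object@k < 1L) return("k must be >= 1")
  if (object@maxIter < 1L) return("maxIter must be >= 1")
  if (!is.finite(object@tol) || object@tol <= 0) return("tol must be > 0")
  if (!(object@init %in% c("farthest_point", "random")))
    return("init must be 'farthest_point' or 'random'")
  TRUE
})

#' Construct a KMeansConfig
#' @param k number of clusters; 8 reproduces the published segmentation.
#' @param maxIter maximum Lloyd iterations.
#' @param tol convergence threshold on the maximal centroid shift.
#' @param seed RNG seed (only consulted when \code{init = "random"}).
#' @param init centroid initialization strategy.
#' @return A \linkS4class{KMeansConfig}.
#' @export
kmeansConfig <- function(k = 8L, maxIter = 300L, tol = 1e-6, seed = 1L,
                         init = c("farthest_point", "random")) {
  init <- match.arg(init)
  new("KMeansConfig", k = as.integer(k), maxIter = as.integer(maxIter),
      tol = as.numeric(tol), seed = as.integer(seed), init = init)
}

#' ClusterModel: fitted K-means state
#'
#' @slot centroids k x d matrix of cluster centroids.
#' @slot labels integer cluster assignment per point (1..k).
#' @slot objective final within-cluster sum of squared Euclidean distances.
#' @slot nIter Lloyd iterations used.
#' @slot objectiveTrace objective value after each iteration (non-increasing).
#' @export
setClass("ClusterModel",
  representation(
    centroids = "matrix",
    labels = "integer",
    objective = "numeric",
    nIter = "integer",
    objectiveTrace = "numeric"
  )
)

setValidity("ClusterModel", function(object) {
  k <- nrow(object@centroids)
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > k))
    return("labels must lie in 1..k")
  if (!is.finite(object@objective) || object@objective < 0)
    return("objective must be finite and >= 0")
  TRUE
})

#' DelineationMask: binary malignant map with boundary contours
#'
#' @slot malignant logical matrix marking pixels of malignant clusters.
#' @slot contours list of closed polylines; each a 2-column (row, col) matrix
#'   whose first and last vertices coincide.
#' @slot threshold centroid threshold used to label malignant clusters.
#' @export
setClass("DelineationMask",
  representation(malignant = "matrix", contours = "list",
                 threshold = "numeric")
)

#' DecayCurve: uniformly sampled fluorescence decay
#'
#' @slot t time axis, strictly increasing with constant spacing.
#' @slot y intensity samples.
#' @slot dt sample spacing.
#' @export
setClass("DecayCurve",
  representation(t = "numeric", y = "numeric", dt = "numeric")
)

setValidity("DecayCurve", function(object) {
  n <- length(object@t)
  if (length(object@y) != n) return("t and y must have equal length")
  if (n >= 2L) {
    d <- diff(object@t)
    if (any(d <= 0)) return("t must be strictly increasing")
    if (max(abs(d - object@dt)) > 1e-9 * max(object@dt, 1))
      return("t must be uniformly sampled with spacing dt")
  }
  TRUE
})

#' Construct a DecayCurve
#' @param t uniformly spaced time axis.
#' @param y intensity samples, same length as \code{t}.
#' @return A \linkS4class{DecayCurve}.
#' @export
decayCurve <- function(t, y) {
  t <- as.numeric(t); y <- as.numeric(y)
  dt <- if (length(t) >= 2L) t[2] - t[1] else NA_real_
  new("DecayCurve", t = t, y = y, dt = dt)
}

#' PhantomConfig: parameters of the synthetic phantom generators
#'
#' Defaults encode the study conditions the generators emulate: a 128-band
#' 380-1050 nm cube, an emission peak at 561 nm with tumor amplitude 136 dB vs
#' normal 127 dB, an absorption dip centered at 450 nm spanning 440-460 nm at
#' half depth, ~15\% tumor area and 1 dB additive sensor noise.
#'
#' @slot rows,cols spatial dimensions.
#' @slot nBands number of spectral bands.
#' @slot lambdaMin,lambdaMax spectral range (nm).
#' @slot tumorFraction target tumor area fraction in (0, 0.5].
#' @slot emissionCenter,emissionSigma emission Gaussian center and width (nm).
#' @slot tumorAmpDb,normalAmpDb class emission amplitudes at the peak (dB).
#' @slot absorptionCenter absorption dip center (nm).
#' @slot absorptionHalfwidth half-width at half depth of the dip (nm).
#' @slot noiseSdDb additive Gaussian noise SD (dB).
#' @slot seed RNG seed; phantoms are deterministic given the seed.
#' @export
setClass("PhantomConfig",
  representation(
    rows = "integer", cols = "integer", nBands = "integer",
    lambdaMin = "numeric", lambdaMax = "numeric",
    tumorFraction = "numeric",
    emissionCenter = "numeric", emissionSigma = "numeric",
    tumorAmpDb = "numeric", normalAmpDb = "numeric",
    absorptionCenter = "numeric", absorptionHalfwidth = "numeric",
    noiseSdDb = "numeric", seed = "integer"
  )
)

setValidity("PhantomConfig", function(object) {
  if (object@rows < 4L || object@cols < 4L)
    return("rows and cols must each be >= 4")
  if (object@nBands < 8L) return("nBands must be >= 8")
  if (!(object@lambdaMin < object@emissionCenter &&
        object@emissionCenter < object@lambdaMax))
    return("emissionCenter must lie strictly inside [lambdaMin, lambdaMax]")
  if (object@lambdaMin >= object@lambdaMax)
    return("lambdaMin must be < lambdaMax")
  if (!(object@tumorFraction > 0 && object@tumorFraction <= 0.5))
    return("tumorFraction must lie in (0, 0.5]")
  if (!all(is.finite(c(object@tumorAmpDb, object@normalAmpDb))))
    return("amplitudes must be finite")
  if (object@emissionSigma <= 0 || object@absorptionHalfwidth <= 0)
    return("emissionSigma and absorptionHalfwidth must be > 0")
  if (object@noiseSdDb < 0) return("noiseSdDb must be >= 0")
  TRUE
})

#' Construct a PhantomConfig
#'
#' @param rows,cols spatial dimensions (default 96 x 128).
#' @param nBands spectral bands (default 128).
#' @param lambdaMin,lambdaMax spectral range in nm (defaults 380, 1050).
#' @param tumorFraction target tumor area fraction (default 0.15).
#' @param emissionCenter emission peak center in nm (default 561).
#' @param emissionSigma emission Gaussian SD in nm (default 25).
#' @param tumorAmpDb,normalAmpDb peak amplitudes in dB (defaults 136, 127).
#' @param absorptionCenter absorption dip center in nm (default 450).
#' @param absorptionHalfwidth half-width at half depth in nm (default 10, so
#'   the half-depth band is 440-460 nm).
#' @param noiseSdDb additive noise SD in dB (default 1).
#' @param seed RNG seed (default 42).
#' @return A \linkS4class{PhantomConfig}.
#' @export
phantomConfig <- function(rows = 96L, cols = 128L, nBands = 128L,
                          lambdaMin = 380, lambdaMax = 1050,
                          tumorFraction = 0.15,
                          emissionCenter = 561, emissionSigma = 25,
                          tumorAmpDb = 136, normalAmpDb = 127,
                          absorptionCenter = 450, absorptionHalfwidth = 10,
                          noiseSdDb = 1, seed = 42L) {
  new("PhantomConfig", rows = as.integer(rows), cols = as.integer(cols),
      nBands = as.integer(nBands), lambdaMin = as.numeric(lambdaMin),
      lambdaMax = as.numeric(lambdaMax),
      tumorFraction = as.numeric(tumorFraction),
      emissionCenter = as.numeric(emissionCenter),
      emissionSigma = as.numeric(emissionSigma),
      tumorAmpDb = as.numeric(tumorAmpDb),
      normalAmpDb = as.numeric(normalAmpDb),
      absorptionCenter = as.numeric(absorptionCenter),
      absorptionHalfwidth = as.numeric(absorptionHalfwidth),
      noiseSdDb = as.numeric(noiseSdDb), seed = as.integer(seed))
}

#' Phantom: a synthetic sample with ground truth
#'
#' @slot cube the synthetic \linkS4class{HSCube}.
#' @slot refs \linkS4class{ReferenceFrames} (reflectance phantoms) or NULL.
#' @slot truth logical matrix, TRUE at tumor pixels.
#' @slot config the \linkS4class{PhantomConfig} that generated the phantom.
#' @export
setClass("Phantom",
  representation(cube = "HSCube", refs = "ANY", truth = "matrix",
                 config = "PhantomConfig")
)

setValidity("Phantom", function(object) {
  if (!identical(dim(object@truth), dim(object@cube@data)[1:2]))
    return("truth mask must match the cube's spatial shape")
  frac <- mean(object@truth)
  target <- object@config@tumorFraction
  if (abs(frac - target) > 0.2 * target + 1 / length(object@truth))
    return(sprintf("truth area fraction %.3f outside +/-20%% of target %.3f",
                   frac, target))
  TRUE
})
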