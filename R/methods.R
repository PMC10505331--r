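#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("cubeData", "HSCube", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("wavelengths", "HSCube", function(x) x@wavelength)
#' @rdname accessors
#' @export
setMethod("wavelengths", "SpectralSignature", function(x) x@wavelength)
#' @rdname accessors
#' @export
setMethod("scaleTag", "HSCube", function(x) x@scaleTag)
#' @rdname accessors
#' @export
setMethod("scaleTag", "SpectralSignature", function(x) x@scaleTag)
#' @rdname accessors
#' @export
setMethod("nBands", "HSCube", function(x) dim(x@data)[3])
#' @rdname accessors
#' @export
setMethod("spatialDims", "HSCube", function(x) dim(x@data)[1:2])

#' @rdname accessors
#' @export
setMethod("validMask", "HSCube", function(x) {
  ## a pixel is valid when every band carries a finite value
  apply(is.finite(x@data), c(1, 2), all)
})

#' @rdname accessors
#' @export
setMethod("signatureValues", "SpectralSignature", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("nPixels", "SpectralSignature", function(x) x@nPixels)

#' @rdname accessors
#' @export
setMethod("centroids", "ClusterModel", function(x) x@centroids)
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterModel", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("objectiveValue", "ClusterModel", function(x) x@objective)
#' @rdname accessors
#' @export
setMethod("objectiveTrace", "ClusterModel", function(x) x@objectiveTrace)

#' @rdname accessors
#' @export
setMethod("malignantMask", "DelineationMask", function(x) x@malignant)
#' @rdname accessors
#' @export
setMethod("maskContours", "DelineationMask", function(x) x@contours)
#' @rdname accessors
#' @export
setMethod("thresholdUsed", "DelineationMask", function(x) x@threshold)

#' @rdname accessors
#' @export
setMethod("bandIndex", "MarkerBand", function(x) x@bandIndex)
#' @rdname accessors
#' @export
setMethod("lambdaPeak", "MarkerBand", function(x) x@lambdaPeak)
#' @rdname accessors
#' @export
setMethod("markerDelta", "MarkerBand", function(x) x@delta)

#' @rdname accessors
#' @export
setMethod("lambdaLow", "AbsorptionBand", function(x) x@lambdaLow)
#' @rdname accessors
#' @export
setMethod("lambdaHigh", "AbsorptionBand", function(x) x@lambdaHigh)

#' @rdname accessors
#' @export
setMethod("darkFrame", "ReferenceFrames", function(x) x@dark)
#' @rdname accessors
#' @export
setMethod("whiteFrame", "ReferenceFrames", function(x) x@white)

#' @rdname accessors
#' @export
setMethod("phantomCube", "Phantom", function(x) x@cube)
#' @rdname accessors
#' @export
setMethod("phantomRefs", "Phantom", function(x) x@refs)
#' @rdname accessors
#' @export
setMethod("phantomTruth", "Phantom", function(x) x@truth)
#' @rdname accessors
#' @export
setMethod("phantomConfigOf", "Phantom", function(x) x@config)

setMethod("show", "HSCube", function(object) {
  d <- dim(object@data)
  wl <- object@wavelength
  cat(sprintf("HSCube: %d x %d pixels, %d bands [%s]\n", d[1], d[2], d[3],
              object@scaleTag))
  cat(sprintf("  wavelengths: %.1f - %.1f nm (spacing ~%.2f nm)\n",
              min(wl), max(wl),
              if (length(wl) > 1) mean(diff(wl)) else NA_real_))
  n_na <- sum(is.na(object@data))
  if (n_na > 0) cat(sprintf("  invalid values: %d\n", n_na))
})

setMethod("show", "SpectralSignature", function(object) {
  cat(sprintf("SpectralSignature: %d bands [%s], mean of %d pixels\n",
              length(object@values), object@scaleTag, object@nPixels))
})

setMethod("show", "MarkerBand", function(object) {
  cat(sprintf("MarkerBand: band %d, peak %.2f nm, delta %.3f\n",
              object@bandIndex, object@lambdaPeak, object@delta))
})

setMethod("show", "AbsorptionBand", function(object) {
  cat(sprintf("AbsorptionBand: %.1f - %.1f nm (center %.1f nm)\n",
              object@lambdaLow, object@lambdaHigh,
              (object@lambdaLow + object@lambdaHigh) / 2))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: k = %d, %d points, objective %.6g, %d iterations\n",
              nrow(object@centroids), length(object@labels), object@objective,
              object@nIter))
})

setMethod("show", "DelineationMask", function(object) {
  cat(sprintf("DelineationMask: %d malignant pixels, %d contours, threshold %.3g\n",
              sum(object@malignant), length(object@contours),
              object@threshold))
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@cube@data)
  cat(sprintf("Phantom: %d x %d x %d cube [%s], tumor fraction %.3f, seed %d\n",
              d[1], d[2], d[3], object@cube@scaleTag, mean(object@truth),
              object@config@seed))
})

setMethod("show", "DecayCurve", function(object) {
  cat(sprintf("DecayCurve: %d samples, dt = %.4g\n", length(object@y),
              object@dt))
})
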