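#' @include AllClasses.R
NULL

#' Accessors for hyperLIF objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))
#' @rdname accessors
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))
#' @rdname accessors
#' @export
setGeneric("nBands", function(x) standardGeneric("nBands"))
#' @rdname accessors
#' @export
setGeneric("spatialDims", function(x) standardGeneric("spatialDims"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("signatureValues", function(x) standardGeneric("signatureValues"))
#' @rdname accessors
#' @export
setGeneric("nPixels", function(x) standardGeneric("nPixels"))
#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))
#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))
#' @rdname accessors
#' @export
setGeneric("malignantMask", function(x) standardGeneric("malignantMask"))
#' @rdname accessors
#' @export
setGeneric("maskContours", function(x) standardGeneric("maskContours"))
#' @rdname accessors
#' @export
setGeneric("thresholdUsed", function(x) standardGeneric("thresholdUsed"))
#' @rdname accessors
#' @export
setGeneric("bandIndex", function(x) standardGeneric("bandIndex"))
#' @rdname accessors
#' @export
setGeneric("lambdaPeak", function(x) standardGeneric("lambdaPeak"))
#' @rdname accessors
#' @export
setGeneric("markerDelta", function(x) standardGeneric("markerDelta"))
#' @rdname accessors
#' @export
setGeneric("lambdaLow", function(x) standardGeneric("lambdaLow"))
#' @rdname accessors
#' @export
setGeneric("lambdaHigh", function(x) standardGeneric("lambdaHigh"))
#' @rdname accessors
#' @export
setGeneric("darkFrame", function(x) standardGeneric("darkFrame"))
#' @rdname accessors
#' @export
setGeneric("whiteFrame", function(x) standardGeneric("whiteFrame"))
#' @rdname accessors
#' @export
setGeneric("phantomCube", function(x) standardGeneric("phantomCube"))
#' @rdname accessors
#' @export
setGeneric("phantomRefs", function(x) standardGeneric("phantomRefs"))
#' @rdname accessors
#' @export
setGeneric("phantomTruth", function(x) standardGeneric("phantomTruth"))
#' @rdname accessors
#' @export
setGeneric("phantomConfigOf", function(x) standardGeneric("phantomConfigOf"))

#' Convert intensities to decibels
#'
#' Applies the package's dB convention, \code{20 * log10(value)} referenced to
#' one count. Non-positive values map to the invalid sentinel (\code{NA}).
#' The instrument's dB axis is not tied to a published bit depth, so this
#' reference is a documented package convention; phantom generators
#' parameterize amplitudes directly in dB so published-scale magnitudes
#' (136 dB tumor vs 127 dB normal) are meaningful.
#'
#' @param x an \linkS4class{HSCube} or numeric vector/array.
#' @return Same shape as the input on the dB scale; cubes get
#'   \code{scaleTag "dB"}.
#' @examples
#' toDecibel(c(1, 10, 100))  # 0, 20, 40
#' @export
setGeneric("toDecibel", function(x) standardGeneric("toDecibel"))
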