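#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Mean spectrum over a pixel region
#'
#' Averages the cube over the selected pixels, band by band, skipping invalid
#' (\code{NA}) values. The number of contributing pixels is recorded so that
#' signatures over disjoint regions can be pooled by pixel-count weighting.
#'
#' @param cube an \linkS4class{HSCube}.
#' @param mask logical matrix matching the cube's spatial shape; \code{NULL}
#'   selects the whole image.
#' @return A \linkS4class{SpectralSignature}.
#' @export
regionMeanSpectrum <- function(cube, mask = NULL) {
  stopifnot(is(cube, "HSCube"))
  d <- dim(cube@data)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!identical(dim(mask), d[1:2]))
    .contract_error("mask shape must equal the cube's spatial shape")
  mask <- mask & validMask(cube)
  n <- sum(mask)
  if (n < 1L)
    .contract_error("mask selects no valid pixels")
  flat <- matrix(cube@data, d[1] * d[2], d[3])
  vals <- colMeans(flat[as.vector(mask), , drop = FALSE])
  spectralSignature(cube@wavelength, vals, scaleTag = cube@scaleTag,
                    nPixels = n)
}

#' Histogram, mean and SD of a band image
#'
#' Summary statistics of a single spectral band image: an equal-width
#' histogram over [min, max], the mean, and the population standard deviation
#' (pixel-census semantics: the image is the whole population, so the SD
#' divides by n, not n - 1). Invalid pixels are excluded.
#'
#' @param image 2-D numeric matrix.
#' @param nBins number of histogram bins (default 32).
#' @return A list with \code{breaks}, \code{counts}, \code{mean}, \code{sd},
#'   and \code{n} (valid pixels).
#' @examples
#' bandStatistics(matrix(c(0, 255), 1, 2), nBins = 2)$mean  # 127.5
#' @export
bandStatistics <- function(image, nBins = 32L) {
  v <- as.vector(image)
  v <- v[is.finite(v)]
  if (!length(v)) .contract_error("band image has no valid pixels")
  nBins <- as.integer(nBins)
  stopifnot(nBins >= 1L)
  lo <- min(v); hi <- max(v)
  if (hi > lo) {
    breaks <- seq(lo, hi, length.out = nBins + 1L)
    counts <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE),
                            nBins), nbins = nBins)
  } else {
    breaks <- c(lo, hi)
    counts <- length(v)
  }
  m <- mean(v)
  list(breaks = breaks, counts = counts, mean = m,
       sd = sqrt(mean((v - m)^2)), n = length(v))
}

#' Detect the dominant absorption band of a signature
#'
#' Locates the contiguous wavelength interval around the global absorbance
#' maximum where absorbance exceeds \code{depthFraction} of the peak depth
#' above baseline (baseline = median of the signature). With the default
#' \code{depthFraction = 0.5} this is the full-width-at-half-depth interval:
#' a Gaussian dip centered at 450 nm with half-depth half-width 10 nm yields
#' the 440-460 nm band whose midpoint gives the 450 nm excitation wavelength.
#' Reflectance input is converted to absorbance as \code{-log10(reflectance)}
#' with sentinel propagation; interval endpoints are linearly interpolated
#' between band centers, so they are not quantized to the grid.
#'
#' @param signature a \linkS4class{SpectralSignature} on the reflectance or
#'   absorbance scale.
#' @param depthFraction fraction of peak depth defining the band (default
#'   0.5).
#' @return An \linkS4class{AbsorptionBand}.
#' @export
detectAbsorptionBand <- function(signature, depthFraction = 0.5) {
  stopifnot(is(signature, "SpectralSignature"))
  if (!(signature@scaleTag %in% c("reflectance", "absorbance")))
    .contract_error("signature must be on the reflectance or absorbance scale")
  stopifnot(depthFraction > 0, depthFraction < 1)
  wl <- signature@wavelength
  a <- if (signature@scaleTag == "reflectance") {
    v <- signature@values
    out <- -log10(v)
    out[is.na(v) | v <= 0] <- NA_real_
    out
  } else signature@values
  ok <- is.finite(a)
  if (sum(ok) < 3L) .contract_error("need at least 3 finite bands")
  baseline <- stats::median(a[ok])
  i <- which.max(ifelse(ok, a, -Inf))
  depth <- a[i] - baseline
  if (!is.finite(depth) || depth <= .Machine$double.eps * (abs(baseline) + 1))
    .no_band_error("signature is flat: no absorption band above baseline")
  level <- baseline + depthFraction * depth
  ## walk outwards from the peak while absorbance stays above the level
  lo_i <- i
  while (lo_i > 1L && isTRUE(a[lo_i - 1L] >= level)) lo_i <- lo_i - 1L
  hi_i <- i
  n <- length(a)
  while (hi_i < n && isTRUE(a[hi_i + 1L] >= level)) hi_i <- hi_i + 1L
  lambda_low <- if (lo_i > 1L && is.finite(a[lo_i - 1L])) {
    ## linear interpolation of the crossing between lo_i-1 and lo_i
    wl[lo_i] - (wl[lo_i] - wl[lo_i - 1L]) *
      (a[lo_i] - level) / (a[lo_i] - a[lo_i - 1L])
  } else wl[lo_i]
  lambda_high <- if (hi_i < n && is.finite(a[hi_i + 1L])) {
    wl[hi_i] + (wl[hi_i + 1L] - wl[hi_i]) *
      (a[hi_i] - level) / (a[hi_i] - a[hi_i + 1L])
  } else wl[hi_i]
  if (lambda_low >= lambda_high)
    .no_band_error("absorption band degenerates to a single wavelength")
  absorptionBand(lambda_low, lambda_high)
}

#' Excitation wavelength from an absorption band
#'
#' The excitation laser wavelength is taken as the midpoint of the detected
#' absorption band: (440, 460) nm gives 450 nm, the blue excitation used for
#' the LIF measurements.
#'
#' @param band an \linkS4class{AbsorptionBand}.
#' @return The band midpoint in nm.
#' @export
excitationCenter <- function(band) {
  stopifnot(is(band, "AbsorptionBand"))
  (band@lambdaLow + band@lambdaHigh) / 2
}

#' Select the marker emission band
#'
#' Finds the wavelength of maximal tumor-normal separation: the band index
#' maximizing the absolute difference of the two signatures (ties broken
#' toward the lower wavelength), with the peak wavelength refined by 3-point
#' parabolic interpolation of the absolute difference so it is not quantized
#' to the band grid. On the measured data this selects 561 nm.
#'
#' @param tumor,normal \linkS4class{SpectralSignature}s on a common grid with
#'   at least 3 bands.
#' @return A \linkS4class{MarkerBand}; \code{markerDelta} is the interpolated
#'   tumor minus normal difference at the peak.
#' @export
selectMarkerBand <- function(tumor, normal) {
  stopifnot(is(tumor, "SpectralSignature"), is(normal, "SpectralSignature"))
  wl <- tumor@wavelength
  if (!isTRUE(all.equal(wl, normal@wavelength)))
    .contract_error("tumor and normal signatures must share one grid")
  if (length(wl) < 3L)
    .contract_error("marker selection requires at least 3 bands")
  diff_vals <- tumor@values - normal@values
  adiff <- abs(diff_vals)
  adiff[!is.finite(adiff)] <- -Inf
  mx <- max(adiff)
  if (!is.finite(mx) || mx <= 0)
    .no_marker_error("signatures are identical: no marker band exists")
  i <- which(adiff == mx)[1]  # tie -> lower wavelength
  pk <- .parabolic_peak(wl, adiff, i)
  lambda_peak <- min(max(pk[1], wl[1]), wl[length(wl)])
  delta <- pk[2] * sign(diff_vals[i])
  new("MarkerBand", bandIndex = as.integer(i), lambdaPeak = lambda_peak,
      delta = delta)
}

#' Export a signature as a two-column CSV
#'
#' @param signature a \linkS4class{SpectralSignature}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSignatureCSV <- function(signature, path) {
  utils::write.csv(
    data.frame(wavelength_nm = signature@wavelength,
               value = signature@values),
    path, row.names = FALSE)
  invisible(path)
}

#' Read a signature from a two-column CSV
#'
#' @param path CSV with columns \code{wavelength_nm}, \code{value}.
#' @param scaleTag scale of the stored values.
#' @param nPixels pixel count to record.
#' @return A \linkS4class{SpectralSignature}.
#' @export
readSignatureCSV <- function(path, scaleTag = "raw_counts", nPixels = 1L) {
  df <- utils::read.csv(path)
  spectralSignature(df$wavelength_nm, df$value, scaleTag = scaleTag,
                    nPixels = nPixels)
}
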