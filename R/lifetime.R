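#' @include AllClasses.R utils.R
NULL

#' Normalized cross-correlation of two decay curves
#'
#' Full discrete cross-correlation of the mean-removed signals, normalized by
#' the product of their root sums of squares so a signal correlated against
#' itself peaks at exactly 1 at lag 0. Lag k means the first curve is
#' evaluated k samples later than the second, so a curve that lags its
#' reference peaks at a positive lag.
#'
#' @param a,b \linkS4class{DecayCurve}s with equal sample spacing.
#' @return List with \code{lags} (in time units) and \code{correlation}.
#' @export
crossCorrelation <- function(a, b) {
  stopifnot(is(a, "DecayCurve"), is(b, "DecayCurve"))
  na <- length(a@y); nb <- length(b@y)
  if (na < 2L || nb < 2L)
    .contract_error("curves must have at least 2 samples")
  if (abs(a@dt - b@dt) > 1e-9 * max(a@dt, b@dt))
    .contract_error("curves must share one sample spacing")
  x <- a@y - mean(a@y)
  y <- b@y - mean(b@y)
  sx <- sqrt(sum(x^2)); sy <- sqrt(sum(y^2))
  if (sx == 0 || sy == 0)
    .contract_error("zero-variance input: correlation undefined")
  ## r[k] = sum_i x[i + k] y[i], k = -(na-1) .. (nb-1) reversed; compute via
  ## FFT-backed open convolution of x with reversed y
  r <- stats::convolve(x, y, conj = TRUE, type = "open")
  ## convolve(x, rev(y)) layout: index j corresponds to lag j - nb
  lags_samples <- seq(-(nb - 1L), na - 1L)
  list(lags = lags_samples * a@dt, correlation = r / (sx * sy))
}

#' Estimate the time delay between two decay curves
#'
#' The lag maximizing the normalized cross-correlation, refined by 3-point
#' parabolic interpolation for sub-sample resolution. Positive delay means
#' the signal lags the reference; the estimate is antisymmetric in its
#' arguments and invariant to positive affine scaling of either curve.
#'
#' @param signal,reference \linkS4class{DecayCurve}s with equal spacing.
#' @return Delay in time units.
#' @export
estimateTimeDelay <- function(signal, reference) {
  cc <- crossCorrelation(signal, reference)
  i <- which.max(cc$correlation)
  .parabolic_peak(cc$lags, cc$correlation, i)[1]
}

#' Export a decay curve as two-column CSV
#'
#' @param curve a \linkS4class{DecayCurve}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDecayCSV <- function(curve, path) {
  utils::write.csv(data.frame(t = curve@t, intensity = curve@y), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read a decay curve from two-column CSV
#'
#' @param path CSV with columns \code{t}, \code{intensity}.
#' @return A \linkS4class{DecayCurve}.
#' @export
readDecayCSV <- function(path) {
  df <- utils::read.csv(path)
  decayCurve(df$t, df$intensity)
}
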