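#' @include AllClasses.R AllGenerics.R utils.R cube-io.R
NULL

## Smooth random field via FFT-based circular Gaussian blur of white noise,
## standardized to zero mean / unit SD. Thresholding its upper quantile yields
## irregular blob-shaped regions with exactly the requested area fraction.
.smooth_field <- function(rows, cols, sigma_px = 8) {
  noise <- matrix(stats::rnorm(rows * cols), rows, cols)
  gr <- stats::dnorm(pmin(0:(rows - 1), rows - (0:(rows - 1))), sd = sigma_px)
  gc <- stats::dnorm(pmin(0:(cols - 1), cols - (0:(cols - 1))), sd = sigma_px)
  kern <- outer(gr, gc)
  kern <- kern / sum(kern)
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) /
    (rows * cols)
  (sm - mean(sm)) / stats::sd(as.vector(sm))
}

.tumor_mask <- function(config) {
  field <- .smooth_field(config@rows, config@cols)
  cut <- stats::quantile(as.vector(field), 1 - config@tumorFraction,
                         type = 1)
  field > cut
}

.wavelength_grid <- function(config) {
  seq(config@lambdaMin, config@lambdaMax, length.out = config@nBands)
}

#' Generate a synthetic LIF emission phantom
#'
#' Emulates the emission structure of the measured LIF cubes: irregular tumor
#' blobs (thresholded smoothed noise, area fraction \code{tumorFraction}),
#' per-pixel emission spectra in dB equal to the class amplitude times a
#' Gaussian band (center \code{emissionCenter}, SD \code{emissionSigma}), plus
#' additive Gaussian sensor noise of SD \code{noiseSdDb}. Defaults encode the
#' reported conditions: 128 bands over 380-1050 nm, peak at 561 nm, tumor
#' 136 dB vs normal 127 dB, 1 dB noise. Deterministic given
#' \code{config@seed}.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @return A \linkS4class{Phantom} whose cube has \code{scaleTag "dB"}.
#' @examples
#' ph <- generateLifPhantom(phantomConfig(rows = 24, cols = 32, nBands = 32))
#' mean(phantomTruth(ph))
#' @export
generateLifPhantom <- function(config = phantomConfig()) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  .with_seed(config@seed, {
    mask <- .tumor_mask(config)
    wl <- .wavelength_grid(config)
    shape <- exp(-(wl - config@emissionCenter)^2 /
                   (2 * config@emissionSigma^2))
    amp <- matrix(config@normalAmpDb, config@rows, config@cols)
    amp[mask] <- config@tumorAmpDb
    cube_arr <- outer(amp, shape)
    if (config@noiseSdDb > 0)
      cube_arr <- cube_arr + array(
        stats::rnorm(length(cube_arr), sd = config@noiseSdDb),
        dim(cube_arr))
    new("Phantom",
        cube = HSCube(cube_arr, wl, scaleTag = "dB"),
        refs = NULL, truth = mask, config = config)
  })
}

#' Generate a synthetic reflectance phantom with reference frames
#'
#' Emulates the broadband absorbance scan: a white reference (flat high
#' counts modulated by a smooth multiplicative shading field), a constant
#' dark reference, and a raw cube equal to
#' \code{dark + (white - dark) * R(lambda, class)} plus count noise. The
#' class reflectance carries a Gaussian absorption dip expressed directly in
#' absorbance units, \code{R = R0 * 10^(-depth * g(lambda))}, so the
#' half-depth absorbance band is exactly \code{absorptionCenter +/-
#' absorptionHalfwidth} (440-460 nm by default) and the tumor dip (depth
#' 0.30) is deeper than the normal one (0.15). Because raw and white share
#' the shading field, Eq.-style calibration cancels it exactly. Count noise
#' SD is \code{5 * noiseSdDb} counts (zero when noise is disabled).
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @param dipDepthTumor,dipDepthNormal absorbance depths of the class dips.
#' @return A \linkS4class{Phantom} with \code{refs} populated and a
#'   \code{raw_counts} cube.
#' @export
generateReflectancePhantom <- function(config = phantomConfig(),
                                       dipDepthTumor = 0.30,
                                       dipDepthNormal = 0.15) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  .with_seed(config@seed, {
    mask <- .tumor_mask(config)
    wl <- .wavelength_grid(config)
    ## half-width at half depth -> Gaussian sigma
    sigma <- config@absorptionHalfwidth / sqrt(2 * log(2))
    g <- exp(-(wl - config@absorptionCenter)^2 / (2 * sigma^2))
    r0 <- 0.8
    shading <- 1 + 0.15 * .smooth_field(config@rows, config@cols, 16)
    shading <- pmax(shading, 0.5)
    white2d <- 3000 * shading
    dark2d <- matrix(100, config@rows, config@cols)
    depth <- matrix(dipDepthNormal, config@rows, config@cols)
    depth[mask] <- dipDepthTumor
    nb <- config@nBands
    refl <- array(NA_real_, c(config@rows, config@cols, nb))
    for (b in seq_len(nb))
      refl[, , b] <- r0 * 10^(-depth * g[b])
    raw <- array(dark2d, c(config@rows, config@cols, nb)) +
      array(white2d - dark2d, c(config@rows, config@cols, nb)) * refl
    noise_sd <- 5 * config@noiseSdDb
    if (noise_sd > 0)
      raw <- raw + array(stats::rnorm(length(raw), sd = noise_sd), dim(raw))
    new("Phantom",
        cube = HSCube(raw, wl, scaleTag = "raw_counts"),
        refs = referenceFrames(dark = dark2d, white = white2d),
        truth = mask, config = config)
  })
}

#' Generate a matched pair of fluorescence decay curves
#'
#' Builds a reference excitation pulse and two decay curves, each the pulse
#' convolved with an exponential kernel \code{exp(-t/tau)}; the tumor curve is
#' additionally shifted by \code{delay} (linear interpolation for fractional
#' sample shifts). In \code{pulse = "delta"} mode the reference is a unit
#' impulse at t = 0, so a noiseless decay equals \code{exp(-t/tau)} exactly
#' and its value at t = tau is 1/e.
#'
#' @param tauTumor,tauNormal decay time constants (> 0).
#' @param delay tumor shift in time units.
#' @param dt sample spacing (> 0).
#' @param n number of samples (>= 16).
#' @param seed RNG seed for the additive noise.
#' @param noiseSd Gaussian noise SD (default 0).
#' @param pulse \code{"delta"} or \code{"gaussian"} excitation pulse.
#' @return List with \code{reference}, \code{tumor}, \code{normal}
#'   \linkS4class{DecayCurve}s.
#' @export
generateDecayPair <- function(tauTumor, tauNormal, delay = 0, dt = 1,
                              n = 256L, seed = 1L, noiseSd = 0,
                              pulse = c("delta", "gaussian")) {
  pulse <- match.arg(pulse)
  if (tauTumor <= 0 || tauNormal <= 0 || dt <= 0)
    .contract_error("taus and dt must be > 0")
  n <- as.integer(n)
  if (n < 16L) .contract_error("n must be >= 16")
  t <- (0:(n - 1L)) * dt
  p <- if (pulse == "delta") {
    c(1, rep(0, n - 1L))
  } else {
    stats::dnorm(t, mean = 5 * dt, sd = 2 * dt) * dt
  }
  decay_of <- function(tau) {
    kern <- exp(-t / tau)
    ## causal discrete convolution, truncated to n samples
    full <- stats::convolve(p, rev(kern), type = "open")
    full[seq_len(n)]
  }
  shift_frac <- function(y, lag_samples) {
    ## positive lag delays the curve; linear interpolation off-grid
    idx <- seq_len(n) - lag_samples
    stats::approx(seq_len(n), y, xout = idx, yleft = 0, yright = 0)$y
  }
  .with_seed(seed, {
    y_n <- decay_of(tauNormal)
    y_t <- shift_frac(decay_of(tauTumor), delay / dt)
    if (noiseSd > 0) {
      y_t <- y_t + stats::rnorm(n, sd = noiseSd)
      y_n <- y_n + stats::rnorm(n, sd = noiseSd)
    }
    list(reference = decayCurve(t, p),
         tumor = decayCurve(t, y_t),
         normal = decayCurve(t, y_n))
  })
}
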