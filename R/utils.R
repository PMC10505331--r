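## Classed conditions so callers and tests can distinguish contract violations
## from format and degenerate-data failures.

.contract_error <- function(msg) {
  stop(errorCondition(msg, class = c("hyperLIF_contract_error",
                                     "hyperLIF_error", "error", "condition")))
}

.format_error <- function(msg) {
  stop(errorCondition(msg, class = c("hyperLIF_format_error",
                                     "hyperLIF_error", "error", "condition")))
}

.no_band_error <- function(msg) {
  stop(errorCondition(msg, class = c("hyperLIF_no_band_error",
                                     "hyperLIF_error", "error", "condition")))
}

.no_marker_error <- function(msg) {
  stop(errorCondition(msg, class = c("hyperLIF_no_marker_error",
                                     "hyperLIF_error", "error", "condition")))
}

.undefined_metric_error <- function(msg) {
  stop(errorCondition(msg, class = c("hyperLIF_undefined_metric_error",
                                     "hyperLIF_error", "error", "condition")))
}

## Run expr with a local RNG state seeded from `seed`, restoring the caller's
## stream afterwards (generators must not perturb user code).
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

## Rounding half away from zero (8-bit normalization uses this, not banker's
## rounding, so 127.5 -> 128).
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

## 3-point parabolic vertex refinement around index i of series f on grid x
## (uniform spacing). Returns c(x_peak, f_peak); falls back to the sample
## itself at the series ends or when the parabola degenerates.
.parabolic_peak <- function(x, f, i) {
  n <- length(f)
  if (i <= 1L || i >= n) return(c(x[i], f[i]))
  fm <- f[i - 1L]; f0 <- f[i]; fp <- f[i + 1L]
  den <- fm - 2 * f0 + fp
  if (!is.finite(den) || abs(den) < .Machine$double.eps * (abs(f0) + 1))
    return(c(x[i], f[i]))
  h <- x[i + 1L] - x[i]
  delta <- 0.5 * (fm - fp) / den
  ## vertex of the interpolating parabola; |delta| <= 1 when i is a local max
  c(x[i] + delta * h, f0 - 0.25 * (fm - fp) * delta)
}
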