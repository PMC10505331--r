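#' @include AllClasses.R AllGenerics.R cube-io.R spectral-analysis.R
#' @include segmentation.R evaluation.R
NULL

.config_hash <- function(x) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(x, tmp)
  unname(tools::md5sum(tmp))
}

.provenance <- function(config_list, seeds = NULL) {
  list(config_hash = .config_hash(config_list),
       seeds = seeds,
       r_version = as.character(getRversion()),
       package_version = as.character(utils::packageVersion("hyperLIF")))
}

#' Run the absorbance scan phase
#'
#' Phase one of the workflow: calibrate the raw broadband cube against its
#' white/dark references, average the (tumor-region or whole-image)
#' reflectance spectrum, detect the dominant absorption band, and derive the
#' excitation wavelength as its midpoint. On the measured samples this chain
#' yields the 440-460 nm band and the 450 nm blue excitation laser.
#'
#' @param cube raw \linkS4class{HSCube} (\code{scaleTag "raw_counts"}).
#' @param refs \linkS4class{ReferenceFrames}; required.
#' @param mask optional logical region mask (e.g. the tumor area); default is
#'   the whole image.
#' @param depthFraction band depth fraction (see
#'   \code{\link{detectAbsorptionBand}}).
#' @param outputDir optional directory; when given, the signature CSV and a
#'   JSON report are written there.
#' @return List with \code{band} (\linkS4class{AbsorptionBand}),
#'   \code{excitation} (nm) and \code{signature}.
#' @export
runAbsorbancePhase <- function(cube, refs, mask = NULL, depthFraction = 0.5,
                               outputDir = NULL) {
  if (is.null(refs))
    .contract_error("absorbance phase requires reference frames")
  refl <- calibrateReflectance(cube, refs)
  sig <- regionMeanSpectrum(refl, mask)
  band <- detectAbsorptionBand(sig, depthFraction)
  excitation <- excitationCenter(band)
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    writeSignatureCSV(sig, file.path(outputDir, "absorbance_signature.csv"))
    jsonlite::write_json(
      list(band_nm = c(band@lambdaLow, band@lambdaHigh),
           excitation_nm = excitation,
           provenance = .provenance(list(depthFraction = depthFraction))),
      file.path(outputDir, "absorbance_report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(band = band, excitation = excitation, signature = sig)
}

## Class signatures from a truth mask, or - absent pathology guidance - from
## the top/bottom intensity deciles at the brightest band (documented
## surrogate for pathology-guided regions).
.class_signatures <- function(cube, truth = NULL) {
  if (!is.null(truth)) {
    return(list(tumor = regionMeanSpectrum(cube, truth),
                normal = regionMeanSpectrum(cube, !truth)))
  }
  totals <- apply(cube@data, 3, function(m) mean(m, na.rm = TRUE))
  b <- which.max(totals)
  img <- cube@data[, , b]
  qs <- stats::quantile(img, c(0.1, 0.9), na.rm = TRUE)
  list(tumor = regionMeanSpectrum(cube, !is.na(img) & img >= qs[2]),
       normal = regionMeanSpectrum(cube, !is.na(img) & img <= qs[1]))
}

#' Run the LIF delineation phase
#'
#' Phase two of the workflow on an emission cube: derive tumor/normal class
#' signatures (from the truth mask when available, else a top-vs-bottom
#' intensity decile surrogate), select the marker emission band (or honor an
#' override wavelength), segment the marker-band image (8-bit normalization,
#' K-means, centroid threshold, contours), and - when ground truth is
#' supplied - evaluate pixel-level sensitivity and specificity.
#'
#' @param cube emission \linkS4class{HSCube}.
#' @param truth optional logical ground-truth tumor mask.
#' @param config \linkS4class{KMeansConfig} for the clustering stage.
#' @param threshold malignant centroid cutoff (default 1.7).
#' @param rescaleFactor post-normalization rescale (default 0.01).
#' @param markerOverride optional wavelength (nm); skips marker selection and
#'   uses the nearest band.
#' @param outputDir optional directory for artifacts (signatures, mask PNG
#'   and run-length text, contours JSON, metrics JSON).
#' @return List with \code{marker} (\linkS4class{MarkerBand} or NULL when
#'   overridden), \code{bandIndex}, \code{mask}
#'   (\linkS4class{DelineationMask}), \code{counts} and \code{metrics} (NULL
#'   without truth).
#' @export
runLifPhase <- function(cube, truth = NULL, config = kmeansConfig(),
                        threshold = 1.7, rescaleFactor = 0.01,
                        markerOverride = NULL, outputDir = NULL) {
  marker <- NULL
  if (is.null(markerOverride)) {
    sigs <- .class_signatures(cube, truth)
    marker <- selectMarkerBand(sigs$tumor, sigs$normal)
    b <- marker@bandIndex
  } else {
    b <- which.min(abs(cube@wavelength - markerOverride))
  }
  img <- cube@data[, , b]
  mask <- segmentMarkerImage(img, config, threshold, rescaleFactor)
  counts <- NULL
  metrics <- NULL
  if (!is.null(truth)) {
    counts <- confusionCounts(mask@malignant, truth)
    metrics <- metricsFromCounts(counts)
  }
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    writeMaskPNG(mask@malignant, file.path(outputDir, "malignant_mask.png"))
    writeMaskRunLength(mask@malignant,
                       file.path(outputDir, "malignant_mask.runs.tsv"))
    writeContoursJSON(mask@contours, file.path(outputDir, "contours.json"))
    report <- list(
      marker_band_index = b,
      marker_lambda_nm = if (!is.null(marker)) marker@lambdaPeak
                         else cube@wavelength[b],
      threshold = threshold,
      metrics = if (!is.null(metrics)) as.list(metrics) else NULL,
      provenance = .provenance(list(k = config@k, threshold = threshold,
                                    rescaleFactor = rescaleFactor),
                               seeds = config@seed))
    jsonlite::write_json(report, file.path(outputDir, "lif_report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(marker = marker, bandIndex = b, mask = mask, counts = counts,
       metrics = metrics)
}

#' Run the pipeline over a batch of samples
#'
#' Applies \code{\link{runLifPhase}} to each sample and tabulates per-sample
#' sensitivity/specificity with their unweighted averages, mirroring the
#' published ten-sample report layout. Samples that fail are recorded with
#' \code{NA} metrics and the error message; the summary averages the
#' successful rows.
#'
#' @param samples list of \linkS4class{Phantom}s, or of lists with elements
#'   \code{cube} and \code{truth}.
#' @param config,threshold,rescaleFactor passed to \code{\link{runLifPhase}}.
#' @param outputDir optional directory for the per-sample CSV and summary
#'   JSON.
#' @return List with \code{perSample} (data frame: sample, sensitivity,
#'   specificity, fn_ratio, fp_ratio), \code{summary} (mean sensitivity and
#'   specificity) and \code{failures} (character).
#' @export
runBatch <- function(samples, config = kmeansConfig(), threshold = 1.7,
                     rescaleFactor = 0.01, outputDir = NULL) {
  if (!length(samples)) .contract_error("batch requires at least one sample")
  rows <- vector("list", length(samples))
  failures <- character(0)
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    cube <- if (is(s, "Phantom")) s@cube else s$cube
    truth <- if (is(s, "Phantom")) s@truth else s$truth
    res <- tryCatch(
      runLifPhase(cube, truth, config, threshold, rescaleFactor),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("sample %d: %s", i,
                                      conditionMessage(res)))
      rows[[i]] <- data.frame(sample = i, sensitivity = NA_real_,
                              specificity = NA_real_, fn_ratio = NA_real_,
                              fp_ratio = NA_real_)
    } else {
      m <- res$metrics
      rows[[i]] <- data.frame(sample = i,
                              sensitivity = m[["sensitivity"]],
                              specificity = m[["specificity"]],
                              fn_ratio = m[["fn_ratio"]],
                              fp_ratio = m[["fp_ratio"]])
    }
  }
  per_sample <- do.call(rbind, rows)
  ok <- !is.na(per_sample$sensitivity)
  if (!any(ok)) .contract_error("all samples in the batch failed")
  summary <- summarizeSamples(per_sample[ok, ])
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per_sample, file.path(outputDir, "batch_metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(summary = as.list(summary), failures = failures,
           provenance = .provenance(list(k = config@k,
                                         threshold = threshold,
                                         rescaleFactor = rescaleFactor,
                                         n_samples = length(samples)))),
      file.path(outputDir, "batch_summary.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(perSample = per_sample, summary = summary, failures = failures)
}
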