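# hyperLIF

Label-free laser-induced fluorescence (LIF) hyperspectral imaging can
delineate breast tumors without exogenous dyes: endogenous fluorophores
(NADH, FAD, collagen, porphyrins) respond differently to blue-laser
excitation in malignant and normal tissue, and the emitted spectrum carries
that difference. `hyperLIF` implements the complete computational side of
such a workflow for R users working with hyperspectral cubes — from raw
camera frames to a contoured malignancy map with pixel-level accuracy
metrics — together with seeded synthetic phantoms so the whole chain is
testable without instrument data.

The workflow has two phases:

1. **Absorbance scan.** A broadband-illuminated cube is calibrated against
   white/dark references,

   I_fc = (I_oc − I_Dc) / (I_Bc − I_Dc),

   the region-mean reflectance spectrum is converted to absorbance
   (−log₁₀ R), and the dominant absorption band is located as the
   full-width-at-half-depth interval around the absorbance peak. Its
   midpoint chooses the excitation laser: a 440–460 nm band gives 450 nm
   (blue).

2. **LIF delineation.** On the emission cube the marker band is the
   wavelength maximizing the tumor–normal intensity difference
   (argmax_λ |S_tumor(λ) − S_normal(λ)|, refined by 3-point parabolic
   interpolation → 561 nm); the marker-band image is min–max normalized to
   8 bits, rescaled to [0, 2.55], clustered by from-scratch Lloyd K-means
   with K = 8 (deterministic farthest-point initialization), and every
   cluster whose centroid ≥ 1.7 is labeled malignant. Marching-squares
   contours around the resulting mask delineate the margin, and comparison
   with a ground-truth mask yields TP/TN/FP/FN and the derived
   sensitivity/specificity percentages. Fluorescence-decay cross-correlation
   with sub-sample delay estimation probes the lifetime difference between
   the two tissue classes.

Cubes are S4 `HSCube` objects read and written as ENVI (`.hdr` + raw
binary, BSQ or BIL) or multi-page TIFF with a YAML sidecar. Invalid pixels
are carried as `NA` and excluded from every statistic. The dB convention
throughout is 20·log₁₀(value) referenced to one count.

## Worked example

```r
library(hyperLIF)

## a synthetic LIF sample with known ground truth
ph    <- generateLifPhantom(phantomConfig(seed = 42))
cube  <- phantomCube(ph)
truth <- phantomTruth(ph)

## marker-band selection from class mean spectra
tumor_sig  <- regionMeanSpectrum(cube, truth)
normal_sig <- regionMeanSpectrum(cube, !truth)
selectMarkerBand(tumor_sig, normal_sig)
#> MarkerBand: band 35, peak 560.68 nm, delta 9.020

## full delineation + evaluation
res <- runLifPhase(cube, truth)
round(res$metrics, 2)
#> sensitivity specificity    fn_ratio    fp_ratio
#>      100.00       99.99        0.00        0.01
res$mask
#> DelineationMask: 1844 malignant pixels, 6 contours, threshold 1.7
```

The phantom places the tumor emission amplitude at 136 dB and normal tissue
at 127 dB with 1 dB sensor noise; the recovered class means at the marker
band are 135.73 dB and 126.72 dB (the small offsets from the nominal
amplitudes are the ~5.28 nm band-grid discretization of the 561 nm peak).
The marker peak lands within half a nanometer of the generator's 561 nm
emission center, and the K = 8 / threshold-1.7 segmentation agrees with the
ground truth on essentially every pixel under these noise conditions.

A shell entry point wrapping the same functions (subcommands `simulate`,
`calibrate`, `absorb-scan`, `lif-run`, `evaluate`, `batch`) is installed at
`system.file("scripts", "lif-pipeline.R", package = "hyperLIF")`.

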