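# deblurMSI

Software-only resolution enhancement and resolution *measurement* for
(ambient) mass spectrometry imaging, written for MSI practitioners who
want to deblur ion images and quantify the gain without any extra
acquisitions, reference targets or training data.

An ion image is modelled linearly as

```
I = O ⊗ h + N
```

with `I` the observed image, `O` the object, `h` an isotropic Gaussian
point spread function (PSF) and `N` noise. The package provides:

* **`estimatePSFWidth()`** — the blur width 2σ (pixels) of a single
  image, measured from its own sharp edges: Canny edge detection, Hough
  line extraction, intensity profiles perpendicular to each edge,
  central-difference differentiation, and Gaussian line-spread-function
  fits (accepted when R² > 0.5; the width is the mean of 2σ over
  accepted fits).
* **`autoDeconvolve()`** — blind Richardson–Lucy deconvolution that is
  fully automated by the estimator: the initial PSF is a Gaussian of the
  estimated width, and after a minimum of 5 iterations the run stops
  when the re-measured width plateaus (|Δ2σ| < 0.01) or starts
  increasing (returning the minimum-width iterate). Images whose width
  is not estimable, or is ≤ 1 px (sub-pixel guard), are returned
  untouched.
* **`singleImageResolution()`** — single-image Fourier ring correlation:
  checkerboard-split the image into two interleaved halves, correlate
  their spectra per frequency ring, intersect with the half-bit
  information threshold `T(n) = (0.2071 + 1.9102/√n)/(1.2071 +
  0.9102/√n)`, and convert the cutoff to micrometres via
  `δx = 2·Δx / fthresh`.
* **`makePhantom()` / `degradeImage()` / `simulateBatch()`** — synthetic
  ground truth (known blur, noise at a target peak SNR, missing pixels)
  so every estimator is testable end to end.
* **`runBatchDeconv()` / `runBatchFRC()` / `pairedWilcoxonOneSided()`**
  — batch orchestration with one-sided Wilcoxon signed-rank
  before/after comparison (exact for ≤ 25 pairs, including ties).
* **I/O** — CSV/TSV matrices, grayscale TIFF/PNG, and imzML 1.1 + ibd
  (`extractIonImage()` sums peaks in an m/z window per pixel;
  `writeSyntheticImzML()` writes round-trippable synthetic datasets).

A thin command-line front end ships in `inst/cli/deblur-msi` with verbs
`simulate`, `estimate-psf`, `deconv`, `frc`, `batch-deconv`, `batch-frc`.

## Worked example

```r
library(deblurMSI)

ph  <- makePhantom(c(64, 64), "squares", seed = 3, pixelSize = 100)
obs <- degradeImage(ph, twoSigma = 4, noiseModel = "poisson",
                    snr = 20, seed = 3)

estimatePSFWidth(obs)
#> PSFEstimate: 2*sigma = 4.015 px (113 of 113 fits accepted)

res <- autoDeconvolve(obs)
res
#> DeconvolutionResult: 28 iterations, stop reason 'plateau'
#>   2*sigma: 4.015 -> 1.784 px

singleImageResolution(obs)
#> FRCResult: fthresh = 0.286 (of original Nyquist)
#>   resolution = 698.73 um at pixel size 100 um
```

Reading: the degraded phantom's measured blur (4.02 px) matches the
simulated truth (2σ = 4); deconvolution reduces it to 1.78 px before the
width change plateaus below 0.01 px per iteration. The FRC cutoff at
0.286 of Nyquist says noise, not sampling, limits this image to ~699 μm
at a 100 μm pixel — deblurring and denoising move that cutoff up.

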