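---
title: "Methods: automated deblurring and resolution measurement for MSI"
author: "deblurMSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated deblurring and resolution measurement for MSI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deblurMSI)
```

## The problem

Ambient mass spectrometry imaging (MSI) produces one low-resolution,
noisy 2-D intensity map per m/z channel (an *ion image*). Hardware
determines pixel size, but the *effective* resolution is further degraded
by the instrument's point spread function (PSF) and by noise. deblurMSI
implements a purely computational restoration pipeline built on the
linear imaging model

$$ I = O \otimes h + N, $$

where $I$ is the observed ion image, $O$ the underlying object, $h$ an
isotropic 2-D Gaussian PSF, and $N$ noise. Three capabilities interlock:

1. **Blur estimation** (`estimatePSFWidth`): the PSF width $2\sigma$
   (pixels) of a single image, measured from its own sharp edges.
2. **Blind deconvolution** (`autoDeconvolve`): Richardson–Lucy (RL)
   blind deconvolution whose starting PSF and stopping rule are both
   supplied by the estimator, so no user input is required.
3. **Resolution measurement** (`singleImageResolution`): single-image
   Fourier ring correlation (FRC) against the half-bit information
   threshold, converted to micrometres via the pixel size.

## Edge-based PSF estimation

A step edge imaged through a Gaussian PSF of standard deviation
$\sigma$ has an erf-shaped intensity profile; its derivative — the line
spread function — is a Gaussian with the same $\sigma$. The estimator
therefore:

1. detects edges with a Canny detector (presmoothing $\sigma$ = 1 px;
   hysteresis thresholds at the 50th/90th percentiles of the gradient
   magnitudes, which makes them invariant to intensity scale);
2. extracts straight segments from the edge map with a Hough line
   transform (angular resolution 1°, minimum length 10 px, maximum
   along-line gap 2 px). We use a *deterministic* accumulator with greedy
   peak extraction rather than a randomized probabilistic transform: on
   the small images typical of MSI the full accumulator is cheap, and a
   seed-free estimator means the deconvolution trajectory is exactly
   reproducible;
3. samples intensity profiles perpendicular to each segment (bilinear
   interpolation, anchor spacing 1 px, half-length 8 px — the
   half-length must exceed the largest blur of interest, here
   $2\sigma \lesssim 8$ px); profiles touching the border or missing
   pixels are skipped;
4. differentiates each profile by central differences, flips the dominant
   lobe positive (edge polarity carries no blur information), and fits
   $A e^{-(x-\mu)^2/2s^2}$ by Levenberg–Marquardt, initialized from the
   lobe's moments;
5. accepts fits with $R^2 > 0.5$ and averages $2\sigma$ over accepted
   fits (unweighted mean; a median option exists but is off by default).

**Discrete-sampling correction.** The central difference over a spacing
of two pixels convolves the true LSF with a width-2 boxcar, inflating
the fitted variance by exactly $1/3\ \mathrm{px}^2$. `fitLSF` therefore
reports $\sigma = \sqrt{\max(s^2 - 1/3,\ 10^{-4})}$. Without this
correction a true $2\sigma = 2$ px would be biased high by ~15%, i.e.
the discretisation would masquerade as blur.

**Estimability.** At least `fit.min_fits = 3` accepted fits are required,
otherwise a `notEstimableError` is signalled. One spurious fit should
never drive a deconvolution; three is the smallest count that gives the
mean any averaging effect. This is the practical SNR gate: noisy images
without clearly defined edges are flagged rather than "restored".

## Blind Richardson–Lucy deconvolution

The RL image update is multiplicative,
$\hat O \leftarrow \hat O \cdot [h^+ \otimes (I / (h \otimes \hat O))]$,
with $h^+$ the 180°-rotated kernel. One *outer* blind iteration performs
one image update with the PSF held fixed, then one PSF update with the
image held fixed (the same formula with the roles exchanged), followed by
clipping the PSF to non-negative, re-centring its centroid (preventing
drift of the restored image) and renormalizing it to sum 1. We chose the
minimal 1+1 alternation; with more inner iterations per outer step the
effective iteration count would no longer be comparable to the 5–50
range over which the stopping rule is calibrated.

Numerical choices: the RL ratio denominator is floored at $10^{-12}$;
convolution is FFT-based with mirror (reflective) padding by default —
tissue edges are non-periodic and reflective padding avoids wrap-around
ringing — and a periodic mode is available in which the update provably
conserves total intensity (used by the conservation tests). The PSF
support is fixed at its initial size, which keeps the blind problem
well-posed. Missing pixels are filled with a growing-window local median
before deconvolution and re-masked (as zeros) in the output.

**Initialisation and termination.** The initial PSF is an isotropic
Gaussian of the estimated width $w_0$ (kernel side: smallest odd integer
$\ge 3 \cdot 2\sigma$). After each outer iteration $k$ the width $w_k$
of the current iterate is re-measured. Once $k \ge 5$ the run stops when

* $|w_k - w_{k-1}| < 0.01$ px — the *plateau* criterion, or
* $w_k - w_{k-1} > 0$ — the *blur-increase* criterion, indicating the
  iteration has begun amplifying noise.

The change is measured against the previous iteration, not against
$w_0$, which matches the plateau reading of the rule. The minimum of 5
iterations exists because the first few widths fluctuate while the PSF
estimate stabilizes. On a blur increase the minimum-width iterate seen is
returned, not the degraded last one: the criterion exists precisely to
avoid handing back a worse image. Two guards precede iteration entirely:
`not_estimable` (no edge evidence) and `subpixel_guard`
($w_0 \le 1$ px — blur below one pixel cannot be deconvolved from
pixel-limited data, so the image is returned untouched). If the width
becomes non-estimable mid-run the best iterate so far is returned with
`stopReason = "not_estimable"`.

## Single-image FRC resolution

FRC measures, per ring of spatial frequency, the correlation between the
spectra of two images of the same scene. With only one image available,
`checkerboardSplit` trims to even dimensions and interleaves pixels into
four sub-images, of which the two *diagonal* ones (even/even and
odd/odd) serve as quasi-independent realizations — e.g. a 35×70 image
yields a 17×35 pair. The anti-diagonal pair can be averaged in
(`pair = "both"`), which is off by default; the $\sqrt2$ sampling offset
between the two diagonal grids is treated as negligible after ring
averaging, and no further spectral correction is applied.

Each sub-image is mean-subtracted (missing pixels zero-filled
afterwards), apodized with a Tukey window ($\alpha = 0.25$; tissue
boundaries are non-periodic and would otherwise leak across the
spectrum), and transformed. Rings are one frequency bin wide with
membership by rounding — the maximum frequency sampling available on
small images — and `nPerRing` counts every complex sample (both Friedel
mates), the convention under which the half-bit threshold

$$ T(n) = \frac{0.2071 + 1.9102/\sqrt n}{1.2071 + 0.9102/\sqrt n} $$

is reproducible bit for bit. $T$ decreases from $\approx 1$ at $n = 1$
to $0.2071/1.2071 \approx 0.1716$ for large rings. The cutoff
$f_{\mathrm{thresh}}$ is the first threshold crossing, linearly
interpolated between ring centres; a curve that never crosses yields 1.0
(Nyquist-limited), and a curve starting below threshold yields the first
ring's frequency with a low-SNR warning.

**Frequency bookkeeping and Eq. for resolution.** The sub-image Nyquist
is half the original image's Nyquist, so a sub-axis cutoff $f_{sub}$
corresponds to $f_{\mathrm{thresh}} = f_{sub}/2$ on the original axis.
Resolution is then

$$ \delta x = \frac{2\,\Delta x}{f_{\mathrm{thresh}}}, $$

with $\Delta x$ the *original* pixel size in μm; the factor is read as
$2/f_{\mathrm{thresh}}$ for dimensional consistency and so that the
Nyquist bound $\delta x \ge 2 \Delta x$ always holds (cutoffs above the
Nyquist frequency would be physically improbable). Sub-images below
32 px on either axis trigger an accuracy warning.

## The synthetic generator

`makePhantom` produces piecewise-constant objects with straight edges of
known position and orientation (squares, stripes, a rotated diamond in
the mixed kind, discs), all edges ≥ 15 px so the default Hough
configuration can find them, with a small seeded placement jitter so
batches are not pixel-identical. `degradeImage` applies the imaging
model in order: Gaussian blur of width `twoSigma`, then noise, then
dropout into the missing mask (exactly `round(d * N)` pixels). Peak SNR
is defined as peak clean intensity over the noise standard deviation *at
that intensity*; for Poisson noise intensities are scaled so that
$\sqrt{\text{peak counts}} = \mathrm{SNR}$, sampled, and scaled back.
All randomness is seeded and restores the caller's RNG state.

The default batch conditions — 30 images, true $2\sigma = 4$ px, Poisson
noise at peak SNR 20, seeds $0..29$ — are the conditions under which the
improvement statistics in the tests and the acceptance script are
computed (64×64 phantoms keep a full batch within minutes on one core).
What the generator does *not* emulate: realistic mass spectra (isotope
patterns, peak shapes), spatially varying or anisotropic PSFs,
structured (non-i.i.d.) noise, and tissue-like texture. Tests passing on
phantoms therefore validate the estimators' correctness and calibration,
not their behaviour on every real tissue morphology.

## Statistics

Before/after comparisons use the one-sided Wilcoxon signed-rank test
(`pairedWilcoxonOneSided`): widths should *decrease* after deblurring,
FRC cutoffs should *increase* after restoration; the direction is stored
in every report. Zero differences are dropped (standard signed-rank
convention; the reported `nPairs` is the post-drop count). For up to 25
informative pairs the exact null distribution is computed by dynamic
programming over doubled midranks — exact even under ties, and verified
against exhaustive sign-assignment enumeration in the tests; larger
samples use the normal approximation with tie and continuity correction
via `stats::wilcox.test`. The statistic is the sum of signed ranks
opposing the null in the direction tested ($W^+$ of `after - before`),
so a uniformly improved batch reports statistic 0.

## Known limitations

* The PSF model is isotropic and spatially invariant; anisotropic
  optics or stage-axis asymmetries violate it.
* Images without straight, high-contrast edges (smooth gradients,
  pure texture) are not estimable by design — FRC still works there.
* The "top channels" selector ranks by total intensity only; real
  tissue/background discrimination needs a user-supplied mask.
* Half-window m/z extraction is a plain sum; no centroiding or
  recalibration is attempted.

## Worked example

```{r example, eval = FALSE}
ph  <- makePhantom(c(64, 64), "squares", seed = 3, pixelSize = 100)
obs <- degradeImage(ph, twoSigma = 4, noiseModel = "poisson",
                    snr = 20, seed = 3)
res <- autoDeconvolve(obs)
res
round(widthTrajectory(res), 2)
singleImageResolution(obs)
```
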