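# Single-image Fourier ring correlation (FRC): the image is split into
# two interleaved checkerboard sub-images, their spectra are correlated
# over rings of spatial frequency, and the crossing with the half-bit
# information threshold defines a noise-limited cutoff frequency, hence a
# physical resolution delta_x = 2 * pixel_size / fthresh.

#' Split an image into two checkerboard sub-images
#'
#' The image is trimmed to even dimensions (dropping the last row/column
#' when odd) and decomposed into four interleaved sub-images by taking
#' every other pixel on both axes; the two diagonal sub-images
#' (even-row/even-col and odd-row/odd-col, 0-based) are returned. They act
#' as two quasi-independent realizations of the same scene, each with
#' twice the pixel size.
#'
#' @param image an [IonImage-class] of at least 8 x 8 pixels.
#' @param antidiagonal return the anti-diagonal pair (even/odd and
#'   odd/even) instead.
#' @return a list of two [IonImage-class] sub-images.
#' @examples
#' img <- IonImage(matrix(runif(35 * 70), 35, 70), pixelSize = 100)
#' lapply(checkerboardSplit(img), dim)  # 17 x 35 each
#' @export
checkerboardSplit <- function(image, antidiagonal = FALSE) {
  stopifnot(is(image, "IonImage"))
  d <- dim(image)
  if (d[1L] < 8L || d[2L] < 8L)
    stop("image is under-sampled: checkerboard split needs at least 8 x 8 pixels")
  nr <- d[1L] - d[1L] %% 2L
  nc <- d[2L] - d[2L] %% 2L
  m <- pixels(image)
  msk <- imageMask(image)
  ps2 <- if (is.na(pixelSize(image))) NA_real_ else 2 * pixelSize(image)
  sub <- function(ri, ci) {
    IonImage(m[ri, ci, drop = FALSE], pixelSize = ps2, mz = mzValue(image),
             mask = msk[ri, ci, drop = FALSE])
  }
  ev_r <- seq(1L, nr, by = 2L); od_r <- seq(2L, nr, by = 2L)
  ev_c <- seq(1L, nc, by = 2L); od_c <- seq(2L, nc, by = 2L)
  if (antidiagonal) list(a = sub(ev_r, od_c), b = sub(od_r, ev_c))
  else list(a = sub(ev_r, ev_c), b = sub(od_r, od_c))
}

#' Compute the Fourier ring correlation curve of an image pair
#'
#' Both images are mean-subtracted (over non-missing pixels; missing
#' pixels are then zero-filled), apodized with a Tukey window, and
#' discrete-Fourier-transformed. For each ring of radial frequency the
#' correlation is `Re(sum(Fa * Conj(Fb))) / sqrt(sum(|Fa|^2) *
#' sum(|Fb|^2))` over the Fourier samples whose rounded radial bin falls
#' on the ring. Ring-centre frequencies are normalized so 1.0 is the
#' Nyquist frequency; `nPerRing` counts all complex samples in the ring
#' (both Friedel mates). The half-bit threshold curve is attached.
#'
#' @param a,b [IonImage-class] objects (or matrices) of identical
#'   dimensions.
#' @param window `"tukey"` (alpha = 0.25, default) or `"none"`.
#' @return an [FRCCurve-class].
#' @export
frcCurve <- function(a, b, window = c("tukey", "none")) {
  window <- match.arg(window)
  am <- if (is(a, "IonImage")) frcPrepare(a) else frcPrepareMatrix(as.matrix(a))
  bm <- if (is(b, "IonImage")) frcPrepare(b) else frcPrepareMatrix(as.matrix(b))
  if (!identical(dim(am), dim(bm)))
    stop("images must have identical dimensions")
  nr <- nrow(am); nc <- ncol(am)
  if (window == "tukey") {
    w <- outer(tukeyWindow(nr, 0.25), tukeyWindow(nc, 0.25))
    am <- am * w
    bm <- bm * w
  }
  FA <- stats::fft(am)
  FB <- stats::fft(bm)

  # normalized radial frequency of each FFT sample: 1.0 = Nyquist per axis
  fAxis <- function(n) {
    k <- seq_len(n) - 1L
    k[k > n / 2] <- k[k > n / 2] - n
    2 * k / n
  }
  fr <- fAxis(nr); fc <- fAxis(nc)
  rad <- sqrt(outer(fr^2, fc^2, `+`))
  nbins <- floor(min(nr, nc) / 2)
  ring <- round(rad * nbins)
  keep <- ring >= 1L & ring <= nbins
  ringv <- factor(ring[keep], levels = seq_len(nbins))

  num <- as.numeric(tapply(Re(FA * Conj(FB))[keep], ringv, sum,
                           default = 0))
  pa <- as.numeric(tapply((Mod(FA)^2)[keep], ringv, sum, default = 0))
  pb <- as.numeric(tapply((Mod(FB)^2)[keep], ringv, sum, default = 0))
  nPer <- as.numeric(table(ringv))
  den <- sqrt(pa * pb)
  vals <- numeric(nbins)
  zero <- den == 0
  if (any(zero & nPer > 0))
    warning("all-zero ring denominator; correlation set to 0 for that ring")
  vals[!zero] <- num[!zero] / den[!zero]
  vals <- pmin(pmax(vals, -1), 1)

  present <- nPer > 0
  new("FRCCurve", freqs = (seq_len(nbins) / nbins)[present],
      values = vals[present], nPerRing = nPer[present],
      threshold = halfBitThreshold(nPer[present]))
}

frcPrepare <- function(img) {
  m <- pixels(img)
  msk <- imageMask(img)
  mu <- mean(m[!msk])
  out <- m - mu
  if (any(msk)) out[msk] <- 0   # zero-fill after mean subtraction
  out
}

frcPrepareMatrix <- function(m) m - mean(m)

#' Half-bit information threshold curve
#'
#' The FRC threshold at which each ring carries half a bit of
#' information: `T(n) = (0.2071 + 1.9102 / sqrt(n)) / (1.2071 + 0.9102 /
#' sqrt(n))`, where `n` is the number of Fourier samples in the ring. The
#' curve decreases from ~1 at `n = 1` towards the asymptote
#' 0.2071 / 1.2071 = 0.1716 for densely sampled rings.
#'
#' @param nPerRing number of Fourier samples per ring (all >= 1).
#' @return threshold values, one per ring.
#' @export
halfBitThreshold <- function(nPerRing) {
  if (any(nPerRing < 1))
    stop("every ring must contain at least one Fourier sample")
  s <- sqrt(nPerRing)
  (0.2071 + 1.9102 / s) / (1.2071 + 0.9102 / s)
}

#' Locate the FRC cutoff frequency
#'
#' Returns the frequency of the first crossing where the correlation
#' falls below the threshold curve, linearly interpolated between the
#' adjacent ring centres. When the correlation never falls below
#' threshold the cutoff is 1.0 (Nyquist); when it starts below threshold
#' at the first ring, the first ring's frequency is returned with a
#' low-SNR warning.
#'
#' @param curve an [FRCCurve-class].
#' @return the cutoff frequency (normalized to the curve's Nyquist).
#' @export
findCutoff <- function(curve) {
  stopifnot(is(curve, "FRCCurve"), length(curve@freqs) > 0)
  d <- curve@values - curve@threshold
  if (d[1L] < 0) {
    warning("FRC below threshold at the first ring: low SNR, cutoff unreliable")
    return(curve@freqs[1L])
  }
  below <- which(d < 0)
  if (!length(below)) return(1.0)
  i <- below[1L]
  f0 <- curve@freqs[i - 1L]; f1 <- curve@freqs[i]
  d0 <- d[i - 1L]; d1 <- d[i]
  f0 + (f1 - f0) * d0 / (d0 - d1)
}

#' Convert a cutoff frequency into a physical resolution
#'
#' Implements `delta_x = 2 * pixelSize / fthresh` with `fthresh`
#' normalized to the Nyquist frequency, so a Nyquist-limited image
#' (`fthresh = 1`) resolves `2 * pixelSize` and lower cutoffs give
#' proportionally worse resolution.
#'
#' @param fthresh cutoff frequency in (0, 1].
#' @param deltaX pixel size in micrometres (> 0).
#' @return resolution in micrometres.
#' @export
resolutionFromCutoff <- function(fthresh, deltaX) {
  if (any(fthresh <= 0) || any(fthresh > 1))
    stop("fthresh must lie in (0, 1]")
  if (any(deltaX <= 0)) stop("deltaX must be positive")
  2 * deltaX / fthresh
}

#' Measure single-image resolution by checkerboard FRC
#'
#' Splits the image with [checkerboardSplit()], computes the FRC between
#' the diagonal sub-image pair, and intersects it with the half-bit
#' threshold. The cutoff found on the sub-image frequency axis is mapped
#' back to the original sampling (the sub-image Nyquist is half the
#' original Nyquist, so the sub-axis cutoff is divided by 2) and the
#' resolution is computed against the ORIGINAL pixel size. A warning is
#' attached when either sub-image dimension is below 32 pixels, which
#' limits accuracy.
#'
#' @param image an [IonImage-class], at least 8 x 8, with `pixelSize` set
#'   (a missing pixel size yields a result in normalized units only).
#' @param window apodization passed to [frcCurve()].
#' @param pair `"diagonal"` (default) uses the even/even-odd/odd pair;
#'   `"both"` averages in the anti-diagonal pair's curve.
#' @return an [FRCResult-class].
#' @export
singleImageResolution <- function(image, window = c("tukey", "none"),
                                  pair = c("diagonal", "both")) {
  stopifnot(is(image, "IonImage"))
  window <- match.arg(window)
  pair <- match.arg(pair)
  halves <- checkerboardSplit(image)
  dsub <- dim(halves$a)
  small <- any(dsub < 32L)
  if (small)
    warning(sprintf(
      "sub-images are %d x %d (< 32 px): limited FRC accuracy", dsub[1L],
      dsub[2L]))
  curve <- frcCurve(halves$a, halves$b, window = window)
  if (pair == "both") {
    anti <- checkerboardSplit(image, antidiagonal = TRUE)
    curve2 <- frcCurve(anti$a, anti$b, window = window)
    vals <- (curve@values + curve2@values) / 2
    curve <- new("FRCCurve", freqs = curve@freqs, values = vals,
                 nPerRing = curve@nPerRing, threshold = curve@threshold)
  }
  lowSNR <- FALSE
  fSub <- withCallingHandlers(
    findCutoff(curve),
    warning = function(w) {
      if (grepl("low SNR", conditionMessage(w))) lowSNR <<- TRUE
    })
  fth <- fSub / 2                       # back to the original Nyquist axis
  dx <- pixelSize(image)
  res <- if (is.na(dx)) NA_real_ else resolutionFromCutoff(fth, dx)
  new("FRCResult", curve = curve, fthresh = fth,
      deltaX = if (is.na(dx)) NA_real_ else dx,
      resolution = res, lowSNR = lowSNR, smallImage = small)
}
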