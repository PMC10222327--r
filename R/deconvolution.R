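# Blind Richardson-Lucy deconvolution driven by the edge-based blur
# estimator: the initial PSF guess is a Gaussian of the estimated width,
# and the iteration stops when the re-estimated width plateaus or starts
# increasing (after a minimum of 5 iterations).

RL_EPS <- 1e-12

#' One multiplicative Richardson-Lucy image update
#'
#' Computes `estimate * [psf+ (x) (observed / (psf (x) estimate))]`, where
#' `psf+` is the 180-degree-rotated kernel and `(x)` is 2-D convolution
#' with the chosen boundary handling. The denominator is floored at a
#' small epsilon; the output is non-negative. With a normalized kernel and
#' periodic boundaries the update conserves total intensity.
#'
#' @param estimate current object estimate ([IonImage-class] or matrix).
#' @param psf a [PSFKernel-class] (or plain kernel matrix).
#' @param observed the observed image (same dimensions as `estimate`).
#' @param boundary `"reflect"` (default) or `"periodic"`.
#' @return the updated estimate, same class as `estimate`.
#' @export
rlUpdate <- function(estimate, psf, observed,
                     boundary = c("reflect", "periodic")) {
  boundary <- match.arg(boundary)
  asImg <- is(estimate, "IonImage")
  e <- if (asImg) pixels(estimate) else as.matrix(estimate)
  o <- if (is(observed, "IonImage")) pixels(observed) else as.matrix(observed)
  k <- if (is(psf, "PSFKernel")) kernelWeights(psf) else as.matrix(psf)
  if (!identical(dim(e), dim(o)))
    stop("estimate and observed must have identical dimensions")
  u <- rlUpdateMatrix(e, k, o, boundary)
  if (asImg)
    IonImage(u, pixelSize = pixelSize(estimate), mz = mzValue(estimate),
             mask = imageMask(estimate))
  else u
}

rlUpdateMatrix <- function(e, k, o, boundary) {
  denom <- fftConv2(e, k, boundary = boundary)
  ratio <- o / pmax(denom, RL_EPS)
  u <- e * fftConv2(ratio, k, boundary = boundary, correlate = TRUE)
  pmax(u, 0)
}

#' One outer iteration of blind Richardson-Lucy deconvolution
#'
#' Performs one RL update of the image holding the PSF fixed, then one RL
#' update of the PSF holding the (updated) image fixed — the roles of
#' image and kernel exchanged. The PSF is then clipped to non-negative,
#' its centroid re-centred on the grid centre, and renormalized to sum 1;
#' its support stays fixed at the initial size.
#'
#' @inheritParams rlUpdate
#' @return a list with elements `estimate` (matrix or [IonImage-class],
#'   matching the input) and `psf` (a [PSFKernel-class]).
#' @export
blindRLIterate <- function(estimate, psf, observed,
                           boundary = c("reflect", "periodic")) {
  boundary <- match.arg(boundary)
  asImg <- is(estimate, "IonImage")
  e <- if (asImg) pixels(estimate) else as.matrix(estimate)
  o <- if (is(observed, "IonImage")) pixels(observed) else as.matrix(observed)
  k <- if (is(psf, "PSFKernel")) kernelWeights(psf) else as.matrix(psf)
  if (!identical(dim(e), dim(o)))
    stop("estimate and observed must have identical dimensions")

  e1 <- rlUpdateMatrix(e, k, o, boundary)

  # PSF update: h <- h * (object+ (*) ratio), evaluated on the kernel
  # support; the overall scale is immaterial because of renormalization.
  pr <- (nrow(k) - 1L) %/% 2L
  pc <- (ncol(k) - 1L) %/% 2L
  denom <- fftConv2(e1, k, boundary = boundary)
  ratio <- o / pmax(denom, RL_EPS)
  factor <- crossCorrPatch(e1, ratio, pr, pc, boundary = boundary)
  k1 <- pmax(k * factor, 0)
  s <- sum(k1)
  if (!is.finite(s) || s <= 0)
    stop("numerical degeneracy: PSF collapsed to zero during blind update")
  k1 <- k1 / s
  k1 <- recenterKernel(k1)

  est <- if (asImg)
    IonImage(e1, pixelSize = pixelSize(estimate), mz = mzValue(estimate),
             mask = imageMask(estimate))
  else e1
  list(estimate = est, psf = PSFKernel(k1))
}

# Shift the kernel by integer offsets so its centroid sits on the grid
# centre (prevents the blind update from drifting the image).
recenterKernel <- function(k) {
  n <- nrow(k)
  ctr <- (n + 1) / 2
  idx <- seq_len(n)
  s <- sum(k)
  cr <- sum(rowSums(k) * idx) / s
  cc <- sum(colSums(k) * idx) / s
  dr <- round(ctr - cr); dc <- round(ctr - cc)
  if (dr == 0 && dc == 0) return(k)
  out <- matrix(0, n, n)
  src_r <- idx - dr; src_c <- idx - dc
  okr <- src_r >= 1 & src_r <= n
  okc <- src_c >= 1 & src_c <= n
  out[idx[okr], idx[okc]] <- k[src_r[okr], src_c[okc]]
  s2 <- sum(out)
  if (s2 <= 0) return(k)
  out / s2
}

#' Automated blind deconvolution with estimator-driven termination
#'
#' The image's blur width `w0` is estimated with [estimatePSFWidth()];
#' when no estimate is possible the image is returned unchanged
#' (`stopReason = "not_estimable"`), and when `w0 <= 1` pixel it is
#' returned unchanged under the sub-pixel guard — blur at or below one
#' pixel cannot be used for further deblurring. Otherwise blind RL
#' iterations start from a Gaussian PSF of width `w0`; after each outer
#' iteration `k` the width `wk` of the current estimate is re-measured
#' and, once at least `minIter` iterations have completed, the algorithm
#' stops when `|wk - w(k-1)| < tol` (plateau) or `wk - w(k-1) > 0` (blur
#' increase). On a blur increase the minimum-width iterate seen is
#' returned rather than the degraded last one. Missing pixels are filled
#' with a local median before deconvolution and re-masked afterwards.
#'
#' @param image an [IonImage-class].
#' @param maxIter maximum number of outer iterations (default 50).
#' @param tol plateau tolerance on the width change in pixels
#'   (default 0.01).
#' @param minIter iterations completed before the termination criterion
#'   becomes effective (default 5).
#' @param boundary convolution boundary handling, `"reflect"` (default)
#'   or `"periodic"`.
#' @param config estimator configuration from [psfConfig()].
#' @return a [DeconvolutionResult-class].
#' @examples
#' \donttest{
#' ph <- makePhantom(c(64, 64), "squares", seed = 3)
#' obs <- degradeImage(ph, twoSigma = 4, noiseModel = "poisson",
#'                     snr = 20, seed = 3)
#' res <- autoDeconvolve(obs)
#' widthTrajectory(res)
#' }
#' @export
autoDeconvolve <- function(image, maxIter = 50L, tol = 0.01, minIter = 5L,
                           boundary = c("reflect", "periodic"),
                           config = psfConfig()) {
  stopifnot(is(image, "IonImage"))
  boundary <- match.arg(boundary)

  est0 <- tryCatch(estimatePSFWidth(image, config),
                   notEstimableError = function(e) NULL)
  w0 <- if (is.null(est0)) NA_real_ else twoSigma(est0)
  if (is.na(w0)) {
    return(new("DeconvolutionResult", restored = image,
               psf = gaussianKernel(1, size = 3L),
               widthTrajectory = numeric(0), iterations = 0L,
               stopReason = "not_estimable"))
  }
  if (w0 <= 1) {
    return(new("DeconvolutionResult", restored = image,
               psf = gaussianKernel(max(w0, 0.1), size = 3L),
               widthTrajectory = w0, iterations = 0L,
               stopReason = "subpixel_guard"))
  }

  msk <- imageMask(image)
  observed <- fillMissing(pixels(image), msk)
  psf <- gaussianKernel(w0)
  est <- observed
  traj <- w0
  bestW <- w0
  bestEst <- est
  bestPSF <- psf
  stopReason <- "max_iter"
  iterations <- 0L

  mkImage <- function(m) IonImage(m, pixelSize = pixelSize(image),
                                  mz = mzValue(image))

  for (k in seq_len(maxIter)) {
    step <- blindRLIterate(est, psf, observed, boundary = boundary)
    est <- step$estimate
    psf <- step$psf
    iterations <- k
    estK <- tryCatch(estimatePSFWidth(mkImage(est), config),
                     notEstimableError = function(e) NULL)
    wk <- if (is.null(estK)) NA_real_ else twoSigma(estK)
    if (is.na(wk)) {
      # edges washed out below the estimator's evidence threshold:
      # keep the best iterate seen and report the estimability loss
      stopReason <- "not_estimable"
      est <- bestEst; psf <- bestPSF
      break
    }
    traj <- c(traj, wk)
    if (wk < bestW) {
      bestW <- wk; bestEst <- est; bestPSF <- psf
    }
    if (k >= minIter) {
      dw <- wk - traj[length(traj) - 1L]
      if (dw > 0) {
        stopReason <- "blur_increase"
        est <- bestEst; psf <- bestPSF
        break
      }
      if (abs(dw) < tol) {
        stopReason <- "plateau"
        break
      }
    }
  }
  if (stopReason == "max_iter" && iterations == maxIter)
    warning(sprintf("termination criterion not met within %d iterations",
                    maxIter))

  restoredMat <- if (is(est, "IonImage")) pixels(est) else est
  restoredMat[msk] <- 0
  restoredImg <- IonImage(restoredMat, pixelSize = pixelSize(image),
                          mz = mzValue(image), mask = msk)
  new("DeconvolutionResult", restored = restoredImg, psf = psf,
      widthTrajectory = traj, iterations = iterations,
      stopReason = stopReason)
}
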