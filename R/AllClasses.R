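#' @import methods
NULL

#' IonImage: a single-channel ion image
#'
#' A 2-D grid of non-negative intensities with optional pixel size (um),
#' m/z label and a logical mask of missing pixels. This is the container
#' for both the observed image \eqn{I} and the underlying object \eqn{O}
#' of the linear imaging model \eqn{I = O \otimes h + N}.
#'
#' @slot pixels numeric matrix of intensities; all non-missing entries are
#'   finite and >= 0.
#' @slot pixelSize length of a pixel side in micrometres (`NA_real_` when
#'   unknown; required for physical-unit resolution).
#' @slot mz mass-to-charge value the channel represents (`NA_real_` when
#'   not applicable).
#' @slot mask logical matrix of the same dimensions; `TRUE` marks a
#'   missing pixel. Masked entries of `pixels` are ignored downstream.
#' @slot metadata free-form list (e.g. phantom ground-truth edge segments).
#'
#' @seealso [IonImage()] for the constructor, [pixels()], [pixelSize()],
#'   [imageMask()].
#' @exportClass IonImage
setClass("IonImage",
  representation(
    pixels = "matrix",
    pixelSize = "numeric",
    mz = "numeric",
    mask = "matrix",
    metadata = "list"
  ),
  prototype(
    pixelSize = NA_real_,
    mz = NA_real_,
    metadata = list()
  )
)

setValidity("IonImage", function(object) {
  p <- object@pixels
  m <- object@mask
  msg <- character()
  if (nrow(p) < 2L || ncol(p) < 2L)
    msg <- c(msg, "pixel grid must have at least 2 rows and 2 columns")
  if (!identical(dim(m), dim(p)))
    msg <- c(msg, "mask dimensions must match pixel dimensions")
  if (!is.logical(m))
    msg <- c(msg, "mask must be logical")
  v <- p[!m]
  if (any(!is.finite(v)) || any(v < 0))
    msg <- c(msg, "all non-missing intensities must be finite and >= 0")
  if (length(object@pixelSize) != 1L)
    msg <- c(msg, "pixelSize must be a single value")
  if (!is.na(object@pixelSize) && object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct an IonImage
#'
#' @param pixels numeric matrix of intensities (non-negative where not
#'   masked).
#' @param pixelSize pixel side length in micrometres, or `NA`.
#' @param mz m/z value of the channel, or `NA`.
#' @param mask optional logical matrix marking missing pixels; defaults to
#'   all `FALSE`. Non-finite entries of `pixels` are masked automatically.
#' @param metadata optional list of free-form metadata.
#' @return an [IonImage-class] object.
#' @examples
#' img <- IonImage(matrix(runif(64), 8, 8), pixelSize = 100)
#' dim(img)
#' @export
IonImage <- function(pixels, pixelSize = NA_real_, mz = NA_real_,
                     mask = NULL, metadata = list()) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(pixels), ncol(pixels))
  } else {
    mask <- as.matrix(mask)
    storage.mode(mask) <- "logical"
  }
  mask <- mask | !is.finite(pixels)
  pixels[mask] <- 0
  new("IonImage", pixels = pixels, pixelSize = as.numeric(pixelSize),
      mz = as.numeric(mz), mask = mask, metadata = metadata)
}

#' IonImageStack: an aligned collection of ion images
#'
#' All member images share dimensions (and normally pixel size); channel
#' identifiers run parallel to the images. Stands in for one MSI dataset's
#' set of per-ion images.
#'
#' @slot images list of [IonImage-class] objects with identical dimensions.
#' @slot channelIds character vector of channel labels (typically m/z
#'   values), same length as `images`.
#' @exportClass IonImageStack
setClass("IonImageStack",
  representation(images = "list", channelIds = "character")
)

setValidity("IonImageStack", function(object) {
  msg <- character()
  if (length(object@images) != length(object@channelIds))
    msg <- c(msg, "channelIds must have one entry per image")
  if (length(object@images)) {
    ok <- vapply(object@images, is, logical(1), class2 = "IonImage")
    if (!all(ok)) {
      msg <- c(msg, "all elements of images must be IonImage objects")
    } else {
      d0 <- dim(object@images[[1L]]@pixels)
      same <- vapply(object@images,
                     function(im) identical(dim(im@pixels), d0), logical(1))
      if (!all(same))
        msg <- c(msg, "all member images must have identical dimensions")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an IonImageStack
#'
#' @param images list of [IonImage-class] objects of identical dimensions.
#' @param channelIds channel labels (coerced to character); defaults to the
#'   images' m/z values, or their indices when those are absent.
#' @return an [IonImageStack-class].
#' @export
IonImageStack <- function(images, channelIds = NULL) {
  if (is(images, "IonImage")) images <- list(images)
  if (is.null(channelIds)) {
    mzs <- vapply(images, function(im) im@mz, numeric(1))
    channelIds <- if (all(is.finite(mzs))) format(mzs, trim = TRUE)
                  else as.character(seq_along(images))
  }
  new("IonImageStack", images = images,
      channelIds = as.character(channelIds))
}

#' PSFKernel: a normalized convolution kernel
#'
#' Small odd-sized square grid of non-negative weights summing to 1; the
#' point spread function \eqn{h} of the linear imaging model.
#'
#' @slot weights numeric matrix, odd-sized square, non-negative, summing
#'   to 1 within 1e-9.
#' @exportClass PSFKernel
setClass("PSFKernel", representation(weights = "matrix"))

setValidity("PSFKernel", function(object) {
  w <- object@weights
  msg <- character()
  if (nrow(w) != ncol(w) || nrow(w) %% 2L == 0L)
    msg <- c(msg, "kernel must be an odd-sized square")
  if (any(!is.finite(w)) || any(w < 0))
    msg <- c(msg, "kernel weights must be finite and >= 0")
  if (abs(sum(w) - 1) > 1e-9)
    msg <- c(msg, "kernel weights must sum to 1 within 1e-9")
  if (length(msg)) msg else TRUE
})

#' Construct a PSFKernel
#'
#' @param weights odd-sized square matrix of non-negative weights; they are
#'   renormalized to sum exactly 1.
#' @return a [PSFKernel-class].
#' @export
PSFKernel <- function(weights) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  s <- sum(weights)
  if (!is.finite(s) || s <= 0)
    stop("kernel weights must have a positive finite sum")
  new("PSFKernel", weights = weights / s)
}

#' PSFEstimate: aggregated blur width with per-fit evidence
#'
#' @slot twoSigma blur width 2*sigma in pixels: the mean of `2 * sigma`
#'   over all accepted Gaussian fits.
#' @slot nAccepted number of accepted fits (R^2 > 0.5, finite positive
#'   sigma).
#' @slot nTotal number of fitted profiles.
#' @slot fits data.frame with one row per fitted profile: `amplitude`,
#'   `center`, `sigma`, `rSquared`, `accepted`.
#' @exportClass PSFEstimate
setClass("PSFEstimate",
  representation(twoSigma = "numeric", nAccepted = "integer",
                 nTotal = "integer", fits = "data.frame")
)

setValidity("PSFEstimate", function(object) {
  msg <- character()
  if (object@nAccepted > object@nTotal)
    msg <- c(msg, "nAccepted cannot exceed nTotal")
  if (object@nAccepted >= 1L &&
      (!is.finite(object@twoSigma) || object@twoSigma <= 0))
    msg <- c(msg, "twoSigma must be positive when fits were accepted")
  if (length(msg)) msg else TRUE
})

#' FRCCurve: a Fourier ring correlation curve
#'
#' @slot freqs ring-center spatial frequencies, strictly increasing within
#'   (0, 1]; 1.0 is the Nyquist frequency of the correlated pair.
#' @slot values FRC correlation per ring, in \[-1, 1\].
#' @slot nPerRing number of complex Fourier samples per ring (Friedel
#'   pairs both counted).
#' @slot threshold half-bit information threshold per ring.
#' @exportClass FRCCurve
setClass("FRCCurve",
  representation(freqs = "numeric", values = "numeric",
                 nPerRing = "numeric", threshold = "numeric")
)

setValidity("FRCCurve", function(object) {
  msg <- character()
  n <- length(object@freqs)
  if (length(object@values) != n || length(object@nPerRing) != n ||
      length(object@threshold) != n)
    msg <- c(msg, "freqs, values, nPerRing and threshold must have equal length")
  if (n && (any(diff(object@freqs) <= 0) ||
            any(object@freqs <= 0) || any(object@freqs > 1 + 1e-12)))
    msg <- c(msg, "freqs must be strictly increasing within (0, 1]")
  if (length(msg)) msg else TRUE
})

#' FRCResult: single-image resolution measurement
#'
#' @slot curve the [FRCCurve-class] computed on the checkerboard sub-image
#'   pair (frequency axis normalized to the sub-image Nyquist).
#' @slot fthresh cutoff frequency normalized to the ORIGINAL image's
#'   Nyquist, in (0, 1].
#' @slot deltaX pixel size of the original image in micrometres.
#' @slot resolution effective resolution `2 * deltaX / fthresh` in
#'   micrometres (never below the Nyquist bound `2 * deltaX`).
#' @slot lowSNR `TRUE` when the FRC starts below threshold at the first
#'   ring.
#' @slot smallImage `TRUE` when either sub-image dimension is below 32
#'   pixels, limiting accuracy.
#' @exportClass FRCResult
setClass("FRCResult",
  representation(curve = "FRCCurve", fthresh = "numeric",
                 deltaX = "numeric", resolution = "numeric",
                 lowSNR = "logical", smallImage = "logical")
)

setValidity("FRCResult", function(object) {
  msg <- character()
  if (object@fthresh <= 0 || object@fthresh > 1)
    msg <- c(msg, "fthresh must lie in (0, 1]")
  if (is.finite(object@deltaX)) {
    if (abs(object@resolution - 2 * object@deltaX / object@fthresh) >
        1e-9 * object@resolution)
      msg <- c(msg, "resolution must equal 2 * deltaX / fthresh")
    if (object@resolution < 2 * object@deltaX - 1e-9)
      msg <- c(msg, "resolution cannot beat the Nyquist bound 2 * deltaX")
  }
  if (length(msg)) msg else TRUE
})

#' DeconvolutionResult: output of the automated blind deconvolution
#'
#' @slot restored the restored [IonImage-class] (same dimensions as the
#'   input, non-negative).
#' @slot psf the final estimated [PSFKernel-class].
#' @slot widthTrajectory estimated blur widths (2*sigma, pixels): the
#'   initial value followed by one value per completed outer iteration.
#' @slot iterations number of completed outer iterations.
#' @slot stopReason one of `"plateau"`, `"blur_increase"`, `"max_iter"`,
#'   `"subpixel_guard"`, `"not_estimable"`.
#' @exportClass DeconvolutionResult
setClass("DeconvolutionResult",
  representation(restored = "IonImage", psf = "PSFKernel",
                 widthTrajectory = "numeric", iterations = "integer",
                 stopReason = "character")
)

setValidity("DeconvolutionResult", function(object) {
  msg <- character()
  reasons <- c("plateau", "blur_increase", "max_iter", "subpixel_guard",
               "not_estimable")
  if (!object@stopReason %in% reasons)
    msg <- c(msg, paste("stopReason must be one of:",
                        paste(reasons, collapse = ", ")))
  if (object@iterations < 5L &&
      !object@stopReason %in% c("subpixel_guard", "not_estimable", "max_iter"))
    msg <- c(msg, "termination before 5 iterations only via guards")
  if (length(msg)) msg else TRUE
})

#' BatchReport: per-image records plus a paired one-sided Wilcoxon test
#'
#' @slot rows data.frame with one row per image: `id`, `widthBefore`,
#'   `widthAfter` (pixels), `iterations`, `stopReason`, `fthreshBefore`,
#'   `fthreshAfter`, `resolutionBefore`, `resolutionAfter` (um),
#'   `elapsed` (seconds); fields not measured are `NA`.
#' @slot wilcoxonStatistic signed-rank statistic (sum of ranks of
#'   differences opposing the alternative; 0 under perfect improvement).
#' @slot pValue one-sided p-value in (0, 1]; `NA` when the test could not
#'   be run.
#' @slot nPairs number of pairs entering the test after dropping
#'   zero differences.
#' @slot direction human-readable alternative hypothesis, e.g.
#'   `"widthAfter < widthBefore"`.
#' @exportClass BatchReport
setClass("BatchReport",
  representation(rows = "data.frame", wilcoxonStatistic = "numeric",
                 pValue = "numeric", nPairs = "integer",
                 direction = "character")
)
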