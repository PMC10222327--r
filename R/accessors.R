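#' @rdname IonImage-class
#' @export
setMethod("pixels", "IonImage", function(x) x@pixels)

#' @rdname IonImage-class
#' @export
setMethod("pixelSize", "IonImage", function(x) x@pixelSize)

#' @rdname IonImage-class
#' @export
setMethod("mzValue", "IonImage", function(x) x@mz)

#' @rdname IonImage-class
#' @export
setMethod("imageMask", "IonImage", function(x) x@mask)

#' @rdname IonImage-class
#' @export
setMethod("dim", "IonImage", function(x) dim(x@pixels))

#' @rdname IonImage-class
#' @export
setMethod("as.matrix", "IonImage", function(x) {
  p <- x@pixels
  p[x@mask] <- NA_real_
  p
})

setMethod("show", "IonImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("IonImage: %d x %d pixels", d[1], d[2]))
  if (!is.na(object@pixelSize))
    cat(sprintf(", pixel size %g um", object@pixelSize))
  if (!is.na(object@mz))
    cat(sprintf(", m/z %g", object@mz))
  cat("\n")
  v <- object@pixels[!object@mask]
  cat(sprintf("  intensity range [%g, %g]", min(v), max(v)))
  nm <- sum(object@mask)
  if (nm > 0)
    cat(sprintf(", %d missing pixel%s (%.1f%%)", nm,
                if (nm == 1) "" else "s", 100 * nm / prod(d)))
  cat("\n")
  invisible(NULL)
})

#' @rdname IonImageStack-class
#' @export
setMethod("images", "IonImageStack", function(x) x@images)

#' @rdname IonImageStack-class
#' @export
setMethod("channelIds", "IonImageStack", function(x) x@channelIds)

#' @rdname IonImageStack-class
#' @export
setMethod("length", "IonImageStack", function(x) length(x@images))

#' @rdname IonImageStack-class
#' @param i index of the channel to extract.
#' @export
setMethod("[[", "IonImageStack", function(x, i) x@images[[i]])

setMethod("show", "IonImageStack", function(object) {
  n <- length(object@images)
  cat(sprintf("IonImageStack: %d channel%s", n, if (n == 1) "" else "s"))
  if (n) {
    d <- dim(object@images[[1]]@pixels)
    cat(sprintf(" of %d x %d pixels", d[1], d[2]))
  }
  cat("\n")
  if (n) {
    shown <- utils::head(object@channelIds, 5L)
    cat("  channels:", paste(shown, collapse = ", "),
        if (n > 5L) "..." else "", "\n")
  }
  invisible(NULL)
})

#' @rdname PSFKernel-class
#' @export
setMethod("kernelWeights", "PSFKernel", function(x) x@weights)

#' @rdname PSFKernel-class
#' @export
setMethod("dim", "PSFKernel", function(x) dim(x@weights))

setMethod("show", "PSFKernel", function(object) {
  d <- nrow(object@weights)
  cat(sprintf("PSFKernel: %d x %d, sum %.9f\n", d, d, sum(object@weights)))
  invisible(NULL)
})

#' @rdname PSFEstimate-class
#' @export
setMethod("twoSigma", "PSFEstimate", function(x) x@twoSigma)

#' @rdname PSFEstimate-class
#' @export
setMethod("psfFits", "PSFEstimate", function(x) x@fits)

setMethod("show", "PSFEstimate", function(object) {
  cat(sprintf("PSFEstimate: 2*sigma = %.3f px (%d of %d fits accepted)\n",
              object@twoSigma, object@nAccepted, object@nTotal))
  invisible(NULL)
})

#' @rdname FRCResult-class
#' @export
setMethod("frcCurveData", "FRCCurve", function(x) {
  data.frame(freq = x@freqs, frc = x@values, nPerRing = x@nPerRing,
             threshold = x@threshold)
})

#' @rdname FRCResult-class
#' @export
setMethod("frcCurveData", "FRCResult", function(x) frcCurveData(x@curve))

#' @rdname FRCResult-class
#' @export
setMethod("cutoffFrequency", "FRCResult", function(x) x@fthresh)

#' @rdname FRCResult-class
#' @export
setMethod("resolutionValue", "FRCResult", function(x) x@resolution)

setMethod("show", "FRCResult", function(object) {
  cat(sprintf("FRCResult: fthresh = %.3f (of original Nyquist)\n",
              object@fthresh))
  if (is.finite(object@deltaX))
    cat(sprintf("  resolution = %.2f um at pixel size %g um\n",
                object@resolution, object@deltaX))
  if (object@lowSNR)
    cat("  warning: FRC below threshold at the first ring (low SNR)\n")
  if (object@smallImage)
    cat("  warning: sub-images < 32 px, limiting accuracy\n")
  invisible(NULL)
})

#' @rdname DeconvolutionResult-class
#' @export
setMethod("restored", "DeconvolutionResult", function(x) x@restored)

#' @rdname DeconvolutionResult-class
#' @export
setMethod("finalPSF", "DeconvolutionResult", function(x) x@psf)

#' @rdname DeconvolutionResult-class
#' @export
setMethod("widthTrajectory", "DeconvolutionResult", function(x)
  x@widthTrajectory)

#' @rdname DeconvolutionResult-class
#' @export
setMethod("stopReason", "DeconvolutionResult", function(x) x@stopReason)

setMethod("show", "DeconvolutionResult", function(object) {
  tr <- object@widthTrajectory
  cat(sprintf("DeconvolutionResult: %d iteration%s, stop reason '%s'\n",
              object@iterations, if (object@iterations == 1) "" else "s",
              object@stopReason))
  if (length(tr) >= 2)
    cat(sprintf("  2*sigma: %.3f -> %.3f px\n", tr[1], tr[length(tr)]))
  else if (length(tr) == 1)
    cat(sprintf("  2*sigma: %.3f px (unchanged)\n", tr[1]))
  invisible(NULL)
})

#' @rdname BatchReport-class
#' @export
setMethod("reportRows", "BatchReport", function(x) x@rows)

setMethod("show", "BatchReport", function(object) {
  cat(sprintf("BatchReport: %d image%s\n", nrow(object@rows),
              if (nrow(object@rows) == 1) "" else "s"))
  cat(sprintf("  one-sided Wilcoxon signed-rank (alternative: %s)\n",
              object@direction))
  if (is.na(object@pValue)) {
    cat("  test not performed (insufficient informative pairs)\n")
  } else {
    cat(sprintf("  W = %g, p = %.3g, n = %d pairs\n",
                object@wilcoxonStatistic, object@pValue, object@nPairs))
  }
  invisible(NULL)
})
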