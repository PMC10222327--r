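#' @rdname IonImage-class
#' @param object,x an object.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname IonImage-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname IonImage-class
#' @export
setGeneric("mzValue", function(x) standardGeneric("mzValue"))

#' @rdname IonImage-class
#' @export
setGeneric("imageMask", function(x) standardGeneric("imageMask"))

#' @rdname IonImageStack-class
#' @param x an object.
#' @export
setGeneric("images", function(x) standardGeneric("images"))

#' @rdname IonImageStack-class
#' @export
setGeneric("channelIds", function(x) standardGeneric("channelIds"))

#' @rdname PSFKernel-class
#' @param x an object.
#' @export
setGeneric("kernelWeights", function(x) standardGeneric("kernelWeights"))

#' @rdname PSFEstimate-class
#' @param x an object.
#' @export
setGeneric("twoSigma", function(x) standardGeneric("twoSigma"))

#' @rdname PSFEstimate-class
#' @export
setGeneric("psfFits", function(x) standardGeneric("psfFits"))

#' @rdname FRCResult-class
#' @param x an object.
#' @export
setGeneric("frcCurveData", function(x) standardGeneric("frcCurveData"))

#' @rdname FRCResult-class
#' @export
setGeneric("cutoffFrequency", function(x) standardGeneric("cutoffFrequency"))

#' @rdname FRCResult-class
#' @export
setGeneric("resolutionValue", function(x) standardGeneric("resolutionValue"))

#' @rdname DeconvolutionResult-class
#' @param x an object.
#' @export
setGeneric("restored", function(x) standardGeneric("restored"))

#' @rdname DeconvolutionResult-class
#' @export
setGeneric("finalPSF", function(x) standardGeneric("finalPSF"))

#' @rdname DeconvolutionResult-class
#' @export
setGeneric("widthTrajectory", function(x) standardGeneric("widthTrajectory"))

#' @rdname DeconvolutionResult-class
#' @export
setGeneric("stopReason", function(x) standardGeneric("stopReason"))

#' @rdname BatchReport-class
#' @param x an object.
#' @export
setGeneric("reportRows", function(x) standardGeneric("reportRows"))
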