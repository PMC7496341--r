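#' Accessors for MARbench classes
#'
#' Small accessor generics so user code never reaches into slots directly.
#'
#' @param object an object of the documented class.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("energies", function(object) standardGeneric("energies"))
#' @rdname accessors
#' @export
setGeneric("muValues", function(object) standardGeneric("muValues"))
#' @rdname accessors
#' @export
setGeneric("fluenceWeights", function(object) standardGeneric("fluenceWeights"))
#' @rdname accessors
#' @export
setGeneric("nViews", function(object) standardGeneric("nViews"))
#' @rdname accessors
#' @export
setGeneric("nBins", function(object) standardGeneric("nBins"))
#' @rdname accessors
#' @export
setGeneric("binSpacing", function(object) standardGeneric("binSpacing"))
#' @rdname accessors
#' @export
setGeneric("fieldOfView", function(object) standardGeneric("fieldOfView"))
#' @rdname accessors
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))
#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("reconMethod", function(object) standardGeneric("reconMethod"))
#' @rdname accessors
#' @export
setGeneric("sinogramValues", function(object) standardGeneric("sinogramValues"))
#' @rdname accessors
#' @export
setGeneric("channelMatrix", function(object) standardGeneric("channelMatrix"))
#' @rdname accessors
#' @export
setGeneric("aucInf", function(object) standardGeneric("aucInf"))
#' @rdname accessors
#' @export
setGeneric("aucUncertainty", function(object) standardGeneric("aucUncertainty"))

#' @rdname accessors
setMethod("energies", "AttenuationTable", function(object) object@energies)
#' @rdname accessors
setMethod("energies", "Spectrum", function(object) object@energies)
#' @rdname accessors
setMethod("muValues", "AttenuationTable", function(object) object@mu)
#' @rdname accessors
setMethod("fluenceWeights", "Spectrum", function(object) object@weights)
#' @rdname accessors
setMethod("nViews", "ProjectionGeometry", function(object) object@nViews)
#' @rdname accessors
setMethod("nBins", "ProjectionGeometry", function(object) object@nBins)
#' @rdname accessors
setMethod("binSpacing", "ProjectionGeometry", function(object) object@binSpacing)
#' @rdname accessors
setMethod("fieldOfView", "ProjectionGeometry", function(object) object@fov)
#' @rdname accessors
setMethod("geometry", "MaterialSinograms", function(object) object@geometry)
#' @rdname accessors
setMethod("geometry", "CountsSinogram", function(object) object@geometry)
#' @rdname accessors
setMethod("geometry", "LogSinogram", function(object) object@geometry)
#' @rdname accessors
setMethod("pixels", "ReconImage", function(object) object@pixels)
#' @rdname accessors
setMethod("pixelSize", "ReconImage", function(object) object@pixelSize)
#' @rdname accessors
setMethod("reconMethod", "ReconImage", function(object) object@method)
#' @rdname accessors
setMethod("sinogramValues", "LogSinogram", function(object) object@values)
#' @rdname accessors
setMethod("sinogramValues", "CountsSinogram", function(object) object@counts)
#' @rdname accessors
setMethod("sinogramValues", "MaterialSinograms", function(object) object@sinograms)
#' @rdname accessors
setMethod("channelMatrix", "ChannelBank", function(object) object@U)
#' @rdname accessors
setMethod("aucInf", "AUCExtrapolation", function(object) object@aucInf)
#' @rdname accessors
setMethod("aucUncertainty", "AUCExtrapolation", function(object)
  c(epsB = object@epsB, epsV = object@epsV, eps = object@eps))

setMethod("show", "AttenuationTable", function(object) {
  cat(sprintf("AttenuationTable: %s, %d energies [%g, %g] keV\n",
              object@material, length(object@energies),
              min(object@energies), max(object@energies)))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %g kVp, %d bins, mean energy %.1f keV\n",
              object@kvp, length(object@energies),
              sum(object@energies * object@weights)))
})

setMethod("show", "ProjectionGeometry", function(object) {
  cat(sprintf(
    "ProjectionGeometry: %d views over [0, pi), %d bins x %.4f cm, fov %g cm\n",
    object@nViews, object@nBins, object@binSpacing, object@fov))
})

setMethod("show", "PhantomInstance", function(object) {
  cat(sprintf(
    paste0("PhantomInstance: %d disks, %d lumps, inset angle %.3f rad, ",
           "signal %s%s\n"),
    nrow(object@disks), length(object@lumpField@widths), object@insetAngle,
    if (object@signalPresent) "present" else "absent",
    if (object@signalPresent)
      sprintf(" (amplitude %.2f x background)", object@signalAmplitude)
    else ""))
})

setMethod("show", "LumpField", function(object) {
  cat(sprintf("LumpField: %d Gaussian lumps (seed %d)\n",
              length(object@widths), object@seed))
})

setMethod("show", "MaterialSinograms", function(object) {
  cat(sprintf("MaterialSinograms: channels [%s], %d x %d\n",
              paste(names(object@sinograms), collapse = ", "),
              object@geometry@nViews, object@geometry@nBins))
})

setMethod("show", "CountsSinogram", function(object) {
  cat(sprintf(
    "CountsSinogram: %d x %d, I0 = %g, s0 = %g, readout sd = %g\n",
    nrow(object@counts), ncol(object@counts), object@I0, object@s0,
    object@readoutSigma))
})

setMethod("show", "LogSinogram", function(object) {
  cat(sprintf("LogSinogram: %d x %d, range [%.3f, %.3f]\n",
              nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
})

setMethod("show", "ReconImage", function(object) {
  cat(sprintf("ReconImage (%s): %d x %d, pixel %.4f cm\n",
              object@method, nrow(object@pixels), ncol(object@pixels),
              object@pixelSize))
})

setMethod("show", "ChannelBank", function(object) {
  cat(sprintf(
    "ChannelBank: %d DDOG channels on %d x %d ROI (sigma0 = %g c/px)\n",
    ncol(object@U), object@roiSide, object@roiSide, object@params$sigma0))
})

setMethod("show", "ChannelOutputs", function(object) {
  cat(sprintf("ChannelOutputs: %d absent / %d present, p = %d\n",
              nrow(object@v1), nrow(object@v2), ncol(object@v1)))
})

setMethod("show", "AntlerFit", function(object) {
  cat(sprintf("AntlerFit: NT = {%s}, %d repetitions\n",
              paste(object@NT, collapse = ", "), nrow(object@resub)))
})

setMethod("show", "AUCExtrapolation", function(object) {
  cat(sprintf(
    "AUCExtrapolation: AUCinf = %.4f (resub %.4f, holdout %.4f), eps = %.4f\n",
    object@aucInf, object@aucInfResub, object@aucInfHoldout, object@eps))
})
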