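#' Accessors for SABGquant classes
#'
#' Slot accessors for \linkS4class{RGBImage}, \linkS4class{RegionOfInterest},
#' \linkS4class{QuantConfig}, \linkS4class{ConditionDataset} and
#' \linkS4class{ComparisonResult}. Use these rather than \code{@}.
#'
#' @param x an object of the documented class
#' @return the slot value
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "RGBImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))
#' @rdname accessors
#' @export
setMethod("bitDepth", "RGBImage", function(x) x@bitDepth)

#' @rdname accessors
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))
#' @rdname accessors
#' @export
setMethod("imageId", "RGBImage", function(x) x@id)

#' @rdname accessors
#' @export
setGeneric("roiLabel", function(x) standardGeneric("roiLabel"))
#' @rdname accessors
#' @export
setMethod("roiLabel", "RegionOfInterest", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("roiKind", function(x) standardGeneric("roiKind"))
#' @rdname accessors
#' @export
setMethod("roiKind", "RegionOfInterest", function(x) x@kind)

#' @rdname accessors
#' @export
setGeneric("roiPolygon", function(x) standardGeneric("roiPolygon"))
#' @rdname accessors
#' @export
setMethod("roiPolygon", "RegionOfInterest", function(x) x@polygon)

#' @rdname accessors
#' @export
setGeneric("pairedBackground", function(x) standardGeneric("pairedBackground"))
#' @rdname accessors
#' @export
setMethod("pairedBackground", "RegionOfInterest", function(x) x@pairedBackground)

#' @rdname accessors
#' @export
setGeneric("bgavScale", function(x) standardGeneric("bgavScale"))
#' @rdname accessors
#' @export
setMethod("bgavScale", "QuantConfig", function(x) x@bgavScale)

#' @rdname accessors
#' @export
setGeneric("conditionLabel", function(x) standardGeneric("conditionLabel"))
#' @rdname accessors
#' @export
setMethod("conditionLabel", "ConditionDataset", function(x) x@conditionLabel)

#' @rdname accessors
#' @export
setGeneric("covariate", function(x) standardGeneric("covariate"))
#' @rdname accessors
#' @export
setMethod("covariate", "ConditionDataset", function(x) x@covariate)

#' @rdname accessors
#' @export
setGeneric("measurements", function(x) standardGeneric("measurements"))
#' @rdname accessors
#' @export
setMethod("measurements", "ConditionDataset", function(x) x@measurements)

#' @rdname accessors
#' @export
setGeneric("testName", function(x) standardGeneric("testName"))
#' @rdname accessors
#' @export
setMethod("testName", "ComparisonResult", function(x) x@testName)

#' @rdname accessors
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))
#' @rdname accessors
#' @export
setMethod("statistic", "ComparisonResult", function(x) x@statistic)

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setMethod("pValue", "ComparisonResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setGeneric("nPerGroup", function(x) standardGeneric("nPerGroup"))
#' @rdname accessors
#' @export
setMethod("nPerGroup", "ComparisonResult", function(x) x@nPerGroup)

setMethod("show", "RGBImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("RGBImage '%s': %d x %d px, %d-bit, channel range [%.4g, %.4g]\n",
              object@id, d[2], d[1], object@bitDepth,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "RegionOfInterest", function(object) {
  cat(sprintf("RegionOfInterest '%s' (%s): %d vertices%s\n",
              object@label, object@kind, nrow(object@polygon),
              if (is.na(object@pairedBackground)) ""
              else sprintf(", paired to '%s'", object@pairedBackground)))
})

setMethod("show", "QuantConfig", function(object) {
  cat(sprintf(
    "QuantConfig: BGAV = %g * ln(CSI/BSI), csiMode=%s, zeroPixelPolicy=%s, warn below n=%d\n",
    object@bgavScale, object@csiMode, object@zeroPixelPolicy,
    object@minCellsWarn))
})

setMethod("show", "ConditionDataset", function(object) {
  s <- summarizeCondition(object)
  cat(sprintf("ConditionDataset '%s'%s: n=%d, mean BGAV %.2f (SD %.2f)\n",
              object@conditionLabel,
              if (is.na(object@covariate)) ""
              else sprintf(" [covariate %g]", object@covariate),
              s$n, s$meanBGAV, s$sdBGAV))
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("ComparisonResult [%s]: statistic = %.6g%s; n = %s\n",
              object@testName, object@statistic,
              if (is.na(object@pValue)) ""
              else sprintf(", p = %.4g", object@pValue),
              paste(object@nPerGroup, collapse = "/")))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(
    "SyntheticSpec: %d x %d px, %d cells, quotient ~ logNormal(%.3g, %.3g), noise SD %.3g, seed %d\n",
    object@width, object@height, object@nCells, object@ratioMu,
    object@ratioSigma, object@noiseSd, object@seed))
})
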