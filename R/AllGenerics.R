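## Accessor generics. Slot access from user code goes through these.

#' @rdname accessors
#' @param x an object of one of the package's S4 classes.
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("sourceLabel", function(x) standardGeneric("sourceLabel"))

#' @rdname accessors
#' @export
setGeneric("amplitude", function(x) standardGeneric("amplitude"))

#' @rdname accessors
#' @export
setGeneric("energyValues", function(x) standardGeneric("energyValues"))

#' @rdname accessors
#' @export
setGeneric("tokens", function(x) standardGeneric("tokens"))

#' @rdname accessors
#' @export
setGeneric("silences", function(x) standardGeneric("silences"))

#' @rdname accessors
#' @export
setGeneric("thetaPercent", function(x) standardGeneric("thetaPercent"))

#' @rdname accessors
#' @export
setGeneric("resolvedEnergy", function(x) standardGeneric("resolvedEnergy"))

#' @rdname accessors
#' @export
setGeneric("typeLabels", function(x) standardGeneric("typeLabels"))

#' @rdname accessors
#' @export
setGeneric("vocabSize", function(x) standardGeneric("vocabSize"))

#' @rdname accessors
#' @export
setGeneric("tokenCount", function(x) standardGeneric("tokenCount"))

#' @rdname accessors
#' @export
setGeneric("lawId", function(x) standardGeneric("lawId"))

#' @rdname accessors
#' @export
setGeneric("curveData", function(x) standardGeneric("curveData"))

#' Accessors for voicelaws classes
#'
#' `sampleRate`, `sourceLabel`, `amplitude`, `energyValues`, `tokens`,
#' `silences`, `thetaPercent`, `resolvedEnergy`, `typeLabels`, `vocabSize`,
#' `tokenCount`, `lawId` and `curveData` extract the corresponding pieces of
#' the package's S4 objects without touching slots directly.
#'
#' @name accessors
#' @return the requested component: scalars for rates/labels/counts, a
#'   `data.frame` for `tokens`, `silences` and `curveData`, numeric vectors
#'   for `amplitude`, `energyValues` and `typeLabels`.
NULL

setMethod("sampleRate", "AmplitudeSeries", function(x) x@rate)
setMethod("sampleRate", "EnergySeries", function(x) x@rate)
setMethod("sampleRate", "EventSequence", function(x) x@rate)
setMethod("sourceLabel", "AmplitudeSeries", function(x) x@sourceLabel)
setMethod("sourceLabel", "EnergySeries", function(x) x@sourceLabel)
setMethod("amplitude", "AmplitudeSeries", function(x) x@samples)
setMethod("energyValues", "EnergySeries", function(x) x@values)
setMethod("tokens", "EventSequence", function(x) x@tokens)
setMethod("silences", "EventSequence", function(x) x@silences)
setMethod("thetaPercent", "ThresholdSpec", function(x) x@thetaPercent)
setMethod("thetaPercent", "EventSequence", function(x) x@threshold@thetaPercent)
setMethod("thetaPercent", "LawCurve", function(x) x@thetaPercent)
setMethod("resolvedEnergy", "ThresholdSpec", function(x) x@resolvedEnergy)
setMethod("resolvedEnergy", "EventSequence", function(x) x@threshold@resolvedEnergy)
setMethod("typeLabels", "TypeSequence", function(x) x@labels)
setMethod("vocabSize", "TypeSequence", function(x) length(unique(x@labels)))
setMethod("tokenCount", "TypeSequence", function(x) length(x@labels))
setMethod("lawId", "LawCurve", function(x) x@lawId)

setMethod("curveData", "LawCurve", function(x) {
  out <- data.frame(lawId = x@lawId, theta = x@thetaPercent,
                    x = x@x, y = x@y)
  if (length(x@xRescaled)) {
    out$xRescaled <- x@xRescaled
    out$yRescaled <- x@yRescaled
  }
  out
})

#' Length methods
#'
#' Number of samples of a series, of tokens of an [EventSequence-class] or
#' [TypeSequence-class], and of points of a [LawCurve-class].
#'
#' @param x the object.
#' @name length-methods
#' @aliases length,AmplitudeSeries-method length,EnergySeries-method
#'   length,EventSequence-method length,TypeSequence-method
#'   length,LawCurve-method
#' @export
setMethod("length", "AmplitudeSeries", function(x) length(x@samples))

#' @export
setMethod("length", "EnergySeries", function(x) length(x@values))

#' @export
setMethod("length", "EventSequence", function(x) nrow(x@tokens))

#' @export
setMethod("length", "TypeSequence", function(x) length(x@labels))

#' @export
setMethod("length", "LawCurve", function(x) length(x@x))
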