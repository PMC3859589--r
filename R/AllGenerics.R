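#' Accessors for metasucc containers
#'
#' @param object a metasucc S4 object.
#' @name accessors
NULL

#' @describeIn accessors unit x species count matrix.
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @describeIn accessors sampling-unit identifiers, in matrix order.
#' @export
setGeneric("sampleUnits", function(object) standardGeneric("sampleUnits"))

#' @describeIn accessors species codes, in matrix order.
#' @export
setGeneric("speciesNames", function(object) standardGeneric("speciesNames"))

#' @describeIn accessors stratum (or pooled strata) of an abundance matrix.
#' @export
setGeneric("stratum", function(object) standardGeneric("stratum"))

#' @describeIn accessors sampled area per unit, square metres.
#' @export
setGeneric("sampledArea", function(object) standardGeneric("sampledArea"))

#' @describeIn accessors per-unit metadata data.frame.
#' @export
setGeneric("unitData", function(object) standardGeneric("unitData"))

#' @describeIn accessors site id -> class label map of a [ClassScheme-class].
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))

#' @describeIn accessors number of sites per class of a [ClassScheme-class].
#' @export
setGeneric("classSizes", function(object) standardGeneric("classSizes"))

#' @describeIn accessors ordination scores matrix.
#' @export
setGeneric("ordScores", function(object) standardGeneric("ordScores"))

#' @describeIn accessors p-value of a permutation test result.
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
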