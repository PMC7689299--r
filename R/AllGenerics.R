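#' @rdname ChannelUniverse-class
#' @param object,x an object.
#' @export
setGeneric("universeGenes", function(x) standardGeneric("universeGenes"))

#' @rdname ModelDESet-class
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))

#' @rdname ModelDESet-class
#' @export
setGeneric("deChannels", function(x) standardGeneric("deChannels"))

#' @rdname ModelDESet-class
#' @export
setGeneric("directions", function(x) standardGeneric("directions"))

#' @rdname OverlapSummary-class
#' @export
setGeneric("exclusiveCounts", function(x) standardGeneric("exclusiveCounts"))

#' @rdname OverlapSummary-class
#' @param k membership threshold.
#' @export
setGeneric("atLeastK", function(x, k) standardGeneric("atLeastK"))

#' @rdname OverlapSummary-class
#' @export
setGeneric("consistentDown", function(x) standardGeneric("consistentDown"))

#' @rdname PermutationResult-class
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname TwoCompartmentEstimate-class
#' @export
setGeneric("totalCapacitance", function(x) standardGeneric("totalCapacitance"))

#' @rdname SpikeTrainStats-class
#' @export
setGeneric("isiCV", function(x) standardGeneric("isiCV"))

#' @rdname SpikeTrainStats-class
#' @export
setGeneric("firingRate", function(x) standardGeneric("firingRate"))

#' @rdname StandardCurve-class
#' @export
setGeneric("efficiency", function(x) standardGeneric("efficiency"))
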