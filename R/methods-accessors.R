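#' @rdname ChannelUniverse-class
#' @export
setMethod("universeGenes", "ChannelUniverse", function(x) x@genes)

#' @rdname ChannelUniverse-class
#' @export
setMethod("length", "ChannelUniverse", function(x) length(x@genes))

#' @rdname ModelDESet-class
#' @export
setMethod("modelId", "ModelDESet", function(x) x@modelId)

#' @rdname ModelDESet-class
#' @export
setMethod("deChannels", "ModelDESet", function(x) x@deChannels)

#' @rdname ModelDESet-class
#' @export
setMethod("directions", "ModelDESet", function(x) x@directions)

#' @rdname ModelDESet-class
#' @export
setMethod("length", "ModelDESet", function(x) length(x@deChannels))

#' @rdname OverlapSummary-class
#' @export
setMethod("exclusiveCounts", "OverlapSummary", function(x) x@exclusiveCounts)

#' @rdname OverlapSummary-class
#' @export
setMethod("atLeastK", "OverlapSummary", function(x, k) {
  key <- as.character(as.integer(k))
  if (!key %in% names(x@atLeastK))
    stop("no at-least-", k, " union stored in this summary")
  x@atLeastK[[key]]
})

#' @rdname OverlapSummary-class
#' @export
setMethod("consistentDown", "OverlapSummary", function(x) x@consistentDown)

#' @rdname PermutationResult-class
#' @export
setMethod("pValue", "PermutationResult", function(x) x@pValue)

#' @rdname TwoCompartmentEstimate-class
#' @export
setMethod("totalCapacitance", "TwoCompartmentEstimate", function(x) x@cTotal)

#' @rdname SpikeTrainStats-class
#' @export
setMethod("isiCV", "SpikeTrainStats", function(x) x@cv)

#' @rdname SpikeTrainStats-class
#' @export
setMethod("firingRate", "SpikeTrainStats", function(x) x@rate)

#' @rdname StandardCurve-class
#' @export
setMethod("efficiency", "StandardCurve", function(x) x@efficiency)

setMethod("show", "ChannelUniverse", function(object) {
  cat("ChannelUniverse of", length(object@genes), "genes")
  if (nzchar(object@label)) cat(" [", object@label, "]", sep = "")
  cat("\n")
})

setMethod("show", "ModelDESet", function(object) {
  nd <- sum(object@directions == "down")
  cat("ModelDESet <", object@modelId, ">: ", length(object@deChannels),
      " DE channel genes (", nd, " down, ",
      length(object@deChannels) - nd, " up)\n", sep = "")
})

setMethod("show", "OverlapSummary", function(object) {
  cat("OverlapSummary over", length(object@models), "models:",
      paste(object@models, collapse = ", "), "\n")
  cat("  union size:", sum(object@exclusiveCounts), "\n")
  cat("  >=", object@kStar, "-of-", length(object@models), " union: ",
      length(object@atLeastK[[as.character(object@kStar)]]),
      " genes (", length(object@consistentDown),
      " consistently down)\n", sep = "")
})

setMethod("show", "PermutationResult", function(object) {
  cat("PermutationResult: observed ", object@observed, ", ",
      object@nGe, "/", object@nSims, " null draws >= observed\n",
      "  p = ", format(object@pValue, digits = 4),
      " (add-one); raw = ", format(object@pRaw, digits = 4),
      "; universe ", object@universeSize,
      ", draws (", paste(object@drawSizes, collapse = ", "),
      "), k* = ", object@kStar, ", seed ", object@seed, "\n", sep = "")
})

setMethod("show", "TraceRecording", function(object) {
  cat("TraceRecording [", object@mode, "]: ", length(object@time),
      " samples at ", object@samplingRate / 1000, " kHz (",
      format(diff(range(object@time)), digits = 4), " s)\n", sep = "")
})

setMethod("show", "TwoExponentialFit", function(object) {
  cat("TwoExponentialFit: A1 = ", format(object@a1, digits = 4),
      " pA, tau1 = ", format(object@tau1, digits = 4),
      " ms; A2 = ", format(object@a2, digits = 4),
      " pA, tau2 = ", format(object@tau2, digits = 4),
      " ms; iSS = ", format(object@iSS, digits = 4), " pA",
      if (object@degenerate) " [DEGENERATE]" else "", "\n", sep = "")
})

setMethod("show", "TwoCompartmentEstimate", function(object) {
  cat("TwoCompartmentEstimate: C1 = ", format(object@c1, digits = 4),
      " pF, C2 = ", format(object@c2, digits = 4),
      " pF, R1 = ", format(object@r1, digits = 4),
      " MOhm, R2 = ", format(object@r2, digits = 4),
      " MOhm; |C1+C2| = ", format(object@cTotal, digits = 4),
      " pF\n", sep = "")
})

setMethod("show", "SpikeTrainStats", function(object) {
  cat("SpikeTrainStats: ", length(object@spikeTimes), " spikes / ",
      object@duration, " s = ", format(object@rate, digits = 4), " Hz; CV ",
      if (object@cvDefined) format(object@cv, digits = 4) else
        "undefined (<3 spikes)", "\n", sep = "")
})

setMethod("show", "StandardCurve", function(object) {
  cat("StandardCurve: slope ", format(object@slope, digits = 5),
      " cycles/log10, intercept ", format(object@intercept, digits = 5),
      ", R^2 ", format(object@rSquared, digits = 4),
      ", efficiency ", format(100 * object@efficiency, digits = 4),
      "%\n", sep = "")
})
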