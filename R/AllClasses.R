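#' @import methods
NULL

#' Channel gene universe
#'
#' A curated set of ion-channel gene symbols (pore-forming alpha subunits)
#' used both to filter differential-expression tables down to channel genes
#' and as the sampling frame for the permutation null.
#'
#' @slot genes character vector of unique, normalized gene symbols.
#' @slot label free-text provenance of the list.
#' @export
setClass("ChannelUniverse",
  representation(genes = "character", label = "character"),
  prototype(label = "")
)

setValidity("ChannelUniverse", function(object) {
  msg <- character()
  if (length(object@genes) == 0L)
    msg <- c(msg, "universe must contain at least one gene")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "universe genes must be unique")
  if (any(!nzchar(object@genes)))
    msg <- c(msg, "universe genes must be non-empty strings")
  if (length(msg)) msg else TRUE
})

#' One model's differentially expressed channel genes
#'
#' The channel genes called differentially expressed in a single ataxia mouse
#' model, with the direction (sign of the log2 fold change) for each gene.
#'
#' @slot modelId model label, e.g. \code{"ATXN1[82Q]"}.
#' @slot deChannels character vector of DE channel gene symbols.
#' @slot directions named character vector (\code{"down"}/\code{"up"}), one
#'   entry per gene in \code{deChannels}.
#' @export
setClass("ModelDESet",
  representation(modelId = "character", deChannels = "character",
                 directions = "character")
)

setValidity("ModelDESet", function(object) {
  msg <- character()
  if (length(object@modelId) != 1L || !nzchar(object@modelId))
    msg <- c(msg, "modelId must be a single non-empty string")
  if (anyDuplicated(object@deChannels))
    msg <- c(msg, "deChannels must be unique")
  if (!setequal(names(object@directions), object@deChannels))
    msg <- c(msg, "directions must be keyed exactly by deChannels")
  if (length(object@directions) &&
      !all(object@directions %in% c("down", "up")))
    msg <- c(msg, "directions must be 'down' or 'up'")
  if (length(msg)) msg else TRUE
})

#' Cross-model overlap summary (UpSet semantics)
#'
#' Exclusive-intersection counts over all nonempty model subsets, the
#' at-least-k membership unions, and the consistently downregulated subset of
#' the headline (k-star) gene list.
#'
#' @slot models model ids in input order.
#' @slot exclusiveCounts named integer vector over all 2^n - 1 nonempty
#'   model subsets (names are \code{"+"}-joined model ids); each gene in the
#'   union is counted in exactly the subset of models where it is DE.
#' @slot atLeastK list mapping k (as character) to the set of genes DE in at
#'   least k models.
#' @slot kStar the headline k.
#' @slot consistentDown genes in the k-star union whose direction is "down"
#'   in every model where they are DE.
#' @export
setClass("OverlapSummary",
  representation(models = "character", exclusiveCounts = "integer",
                 atLeastK = "list", kStar = "integer",
                 consistentDown = "character")
)

setValidity("OverlapSummary", function(object) {
  msg <- character()
  n <- length(object@models)
  if (n < 2L) msg <- c(msg, "need at least two models")
  if (length(object@exclusiveCounts) != 2L^n - 1L)
    msg <- c(msg, "exclusiveCounts must cover all nonempty model subsets")
  if (length(object@atLeastK)) {
    ks <- as.integer(names(object@atLeastK))
    sizes <- lengths(object@atLeastK)
    if (is.unsorted(ks) || any(diff(sizes[order(ks)]) > 0L))
      msg <- c(msg, "at-least-k unions must be nested (non-increasing in k)")
    u1 <- object@atLeastK[[as.character(min(ks))]]
    if (min(ks) == 1L && sum(object@exclusiveCounts) != length(u1))
      msg <- c(msg, "exclusive counts must sum to the union size")
  }
  if (length(msg)) msg else TRUE
})

#' Permutation test result for a cross-model overlap statistic
#'
#' @slot observed observed value of the overlap statistic (size of the
#'   at-least-k union).
#' @slot nSims number of null simulations.
#' @slot nGe number of simulations with statistic >= observed.
#' @slot pValue add-one estimator (nGe + 1) / (nSims + 1).
#' @slot pRaw raw estimator nGe / nSims.
#' @slot seed RNG seed used.
#' @slot universeSize size of the sampling frame.
#' @slot drawSizes per-model numbers of channels sampled.
#' @slot kStar the k of the at-least-k statistic.
#' @export
setClass("PermutationResult",
  representation(observed = "integer", nSims = "integer", nGe = "integer",
                 pValue = "numeric", pRaw = "numeric", seed = "integer",
                 universeSize = "integer", drawSizes = "integer",
                 kStar = "integer")
)

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (object@nGe < 0L || object@nGe > object@nSims)
    msg <- c(msg, "nGe must lie in [0, nSims]")
  if (abs(object@pValue - (object@nGe + 1) / (object@nSims + 1)) > 1e-12)
    msg <- c(msg, "pValue inconsistent with the add-one estimator")
  if (length(msg)) msg else TRUE
})

#' A single electrophysiological recording trace
#'
#' Uniformly sampled time series from a voltage-clamp, current-clamp or
#' cell-attached recording. Currents are in pA, voltages in mV, time in
#' seconds. Voltages are stored as recorded; liquid junction potential
#' correction is applied explicitly downstream and tracked by a metadata
#' flag.
#'
#' @slot time seconds, strictly increasing, uniform step.
#' @slot signal pA (voltage clamp) or mV (current clamp / cell attached).
#' @slot mode one of \code{"voltage_clamp"}, \code{"current_clamp"},
#'   \code{"cell_attached"}.
#' @slot samplingRate Hz, consistent with the time vector.
#' @slot metadata named list: \code{holding_mV}, \code{step_mV},
#'   \code{series_r_start_MOhm}, \code{series_r_end_MOhm},
#'   \code{input_r_MOhm}, \code{sweep_index}, \code{junction_corrected},
#'   \code{injection_onset_s}, ... as the analysis requires.
#' @export
setClass("TraceRecording",
  representation(time = "numeric", signal = "numeric", mode = "character",
                 samplingRate = "numeric", metadata = "list")
)

setValidity("TraceRecording", function(object) {
  msg <- character()
  if (length(object@time) != length(object@signal))
    msg <- c(msg, "time and signal must have equal length")
  if (!object@mode %in% c("voltage_clamp", "current_clamp", "cell_attached"))
    msg <- c(msg, "unknown recording mode")
  if (length(object@time) >= 2L) {
    dt <- diff(object@time)
    if (any(dt <= 0)) msg <- c(msg, "time must be strictly increasing")
    else {
      step <- stats::median(dt)
      if (max(abs(dt - step)) > 1e-6 * step + 1e-12)
        msg <- c(msg, "time step must be uniform")
      # sampling rate must agree with the time vector to within 1 ppm
      if (abs(object@samplingRate * step - 1) > 1e-6)
        msg <- c(msg, "samplingRate inconsistent with time vector")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Double-exponential fit of a capacitative transient
#'
#' Parameters of i(t) = iSS + A1 exp(-t/tau1) + A2 exp(-t/tau2), t measured
#' from the voltage-step onset. By labeling convention tau1 < tau2 (fast
#' proximal component first).
#'
#' @slot a1,a2 amplitudes, pA.
#' @slot tau1,tau2 time constants, ms.
#' @slot iSS steady-state current, pA.
#' @slot deltaV command-step amplitude, mV.
#' @slot rss residual sum of squares, pA^2.
#' @slot converged logical convergence flag.
#' @slot degenerate TRUE when tau1 and tau2 collapsed within tolerance (a
#'   single-exponential fallback is reported in diagnostics).
#' @slot diagnostics list of fit diagnostics (iterations, starts tried,
#'   fallback fit).
#' @export
setClass("TwoExponentialFit",
  representation(a1 = "numeric", tau1 = "numeric", a2 = "numeric",
                 tau2 = "numeric", iSS = "numeric", deltaV = "numeric",
                 rss = "numeric", converged = "logical",
                 degenerate = "logical", diagnostics = "list")
)

setValidity("TwoExponentialFit", function(object) {
  msg <- character()
  if (!object@degenerate) {
    if (object@tau1 <= 0 || object@tau2 <= 0)
      msg <- c(msg, "time constants must be positive")
    if (object@tau1 >= object@tau2)
      msg <- c(msg, "labeling convention requires tau1 < tau2")
  }
  if (object@deltaV == 0) msg <- c(msg, "deltaV must be nonzero")
  if (length(msg)) msg else TRUE
})

#' Two-compartment equivalent-circuit estimate
#'
#' Circuit parameters of the reduced two-compartment Purkinje neuron model
#' derived from a double-exponential transient fit: C1 (soma and main
#' proximal dendrites), C2 (distal dendritic arbor), R1 (pipette access plus
#' proximal internal resistance), R2 (composite internal resistance to the
#' distal arbor). Total cell capacitance is reported as |C1 + C2|.
#'
#' @slot c1,c2 pF.
#' @slot r1,r2 MOhm.
#' @slot cTotal pF, exactly |c1 + c2|.
#' @export
setClass("TwoCompartmentEstimate",
  representation(c1 = "numeric", c2 = "numeric", r1 = "numeric",
                 r2 = "numeric", cTotal = "numeric")
)

setValidity("TwoCompartmentEstimate", function(object) {
  msg <- character()
  vals <- c(object@c1, object@c2, object@r1, object@r2)
  if (any(!is.finite(vals))) msg <- c(msg, "all parameters must be finite")
  if (object@cTotal != abs(object@c1 + object@c2))
    msg <- c(msg, "cTotal must equal |c1 + c2| exactly")
  if (length(msg)) msg else TRUE
})

#' Spike-train statistics
#'
#' Firing rate and interspike-interval (ISI) statistics over a fixed-length
#' recording. The coefficient of variation (CV) uses the sample (n-1)
#' standard deviation and is flagged undefined with fewer than three spikes.
#'
#' @slot spikeTimes seconds.
#' @slot duration seconds.
#' @slot rate Hz (n spikes / duration).
#' @slot isiMean,isiSd ms.
#' @slot cv unitless; NA when undefined.
#' @slot cvDefined logical.
#' @export
setClass("SpikeTrainStats",
  representation(spikeTimes = "numeric", duration = "numeric",
                 rate = "numeric", isiMean = "numeric", isiSd = "numeric",
                 cv = "numeric", cvDefined = "logical")
)

setValidity("SpikeTrainStats", function(object) {
  msg <- character()
  if (object@duration <= 0) msg <- c(msg, "duration must be positive")
  if (object@cvDefined &&
      abs(object@cv - object@isiSd / object@isiMean) > 1e-12 * max(1, object@cv))
    msg <- c(msg, "cv must equal isiSd / isiMean")
  if (length(msg)) msg else TRUE
})

#' qPCR standard curve
#'
#' Ordinary least-squares line of Ct against log10 input quantity (e.g.
#' percent-input dilution), with amplification efficiency
#' 10^(-1/slope) - 1.
#'
#' @slot logQuantities log10 of the input fraction (or copy proxy).
#' @slot cts cycle thresholds.
#' @slot slope cycles per log10 unit (negative).
#' @slot intercept cycles.
#' @slot rSquared coefficient of determination.
#' @slot efficiency fractional amplification efficiency (1 = 100\%).
#' @export
setClass("StandardCurve",
  representation(logQuantities = "numeric", cts = "numeric",
                 slope = "numeric", intercept = "numeric",
                 rSquared = "numeric", efficiency = "numeric")
)

setValidity("StandardCurve", function(object) {
  msg <- character()
  if (length(object@cts) < 3L) msg <- c(msg, "need at least three points")
  if (object@slope >= 0) msg <- c(msg, "slope must be negative")
  if (length(msg)) msg else TRUE
})
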