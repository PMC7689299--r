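#' Detect spikes by threshold crossing
#'
#' Upward crossings of the voltage threshold with a refractory period; the
#' spike peak is the local maximum between the crossing and the return
#' below threshold (or the refractory horizon).
#'
#' @param trace current-clamp or cell-attached
#'   \linkS4class{TraceRecording}.
#' @param threshold crossing threshold, mV (default -20; uncorrected scale
#'   unless the trace is already junction-corrected).
#' @param refractoryMs minimal spacing between detections, ms (default 2).
#' @return list with \code{times} (threshold-crossing times, s),
#'   \code{peakTimes} (s) and \code{peakIndices}.
#' @export
detectSpikes <- function(trace, threshold = -20, refractoryMs = 2) {
  stopifnot(methods::is(trace, "TraceRecording"))
  if (trace@mode == "voltage_clamp")
    stop("spike detection requires a voltage trace")
  v <- trace@signal
  n <- length(v)
  up <- which(v[-1L] >= threshold & v[-n] < threshold) + 1L
  refractory <- refractoryMs / 1000
  times <- peakTimes <- numeric(0)
  peakIdx <- integer(0)
  lastT <- -Inf
  for (ix in up) {
    tcross <- trace@time[ix]
    if (tcross - lastT < refractory) next
    lastT <- tcross
    # search for the peak until the signal drops back below threshold
    jend <- ix
    horizon <- min(n, ix + as.integer(refractoryMs / 1000 *
                                        trace@samplingRate * 3) + 1L)
    while (jend < horizon && v[jend] >= threshold) jend <- jend + 1L
    seg <- ix:jend
    pk <- seg[which.max(v[seg])]
    times <- c(times, tcross)
    peakTimes <- c(peakTimes, trace@time[pk])
    peakIdx <- c(peakIdx, pk)
  }
  list(times = times, peakTimes = peakTimes, peakIndices = peakIdx)
}

#' Spike-train statistics
#'
#' Firing rate, interspike-interval (ISI) mean and sample standard
#' deviation, and the ISI coefficient of variation CV = SD(ISI)/mean(ISI).
#' The CV is flagged undefined with fewer than three spikes (fewer than two
#' intervals).
#'
#' @param spikeTimes spike times, seconds.
#' @param duration recording length, seconds (the standard protocol uses
#'   10 s of cell-attached recording).
#' @return a \linkS4class{SpikeTrainStats}.
#' @export
spikeStats <- function(spikeTimes, duration) {
  if (duration <= 0) stop("duration must be positive")
  spikeTimes <- sort(as.numeric(spikeTimes))
  n <- length(spikeTimes)
  rate <- n / duration
  if (n >= 3L) {
    isi <- diff(spikeTimes) * 1000
    m <- mean(isi); s <- stats::sd(isi)
    methods::new("SpikeTrainStats", spikeTimes = spikeTimes,
                 duration = duration, rate = rate, isiMean = m, isiSd = s,
                 cv = s / m, cvDefined = TRUE)
  } else {
    methods::new("SpikeTrainStats", spikeTimes = spikeTimes,
                 duration = duration, rate = rate, isiMean = NA_real_,
                 isiSd = NA_real_, cv = NA_real_, cvDefined = FALSE)
  }
}

#' Classify a cell's firing behavior
#'
#' Firing cells are labeled \code{irregular} when their ISI CV is strictly
#' greater than the mean + 1 sample standard deviation of the CVs of the
#' corresponding experimental control group, \code{regular} otherwise (a CV
#' exactly at the threshold is regular). Silent cells (no spikes in the
#' cell-attached recording) are labeled \code{non_firing_depol_block} when
#' they could fire a train of more than 5 action potentials on current
#' injection in whole-cell mode, and \code{discarded} otherwise; a silent
#' cell without rescue information is an error. Cells with too few spikes
#' for a defined CV (1-2 spikes) cannot be placed on the CV scale and are
#' labeled \code{discarded} with a reason.
#'
#' @param stats a \linkS4class{SpikeTrainStats} for the cell.
#' @param controlCVs CVs of the control-group cells (non-empty for firing
#'   cells).
#' @param rescueSpikes number of action potentials fired on whole-cell
#'   current injection (silent cells only; NA when not measured).
#' @return list with \code{label}, \code{cv}, \code{controlCvMean},
#'   \code{controlCvSd}, \code{threshold}, \code{reason}.
#' @export
classifyFiring <- function(stats, controlCVs, rescueSpikes = NA) {
  stopifnot(methods::is(stats, "SpikeTrainStats"))
  silent <- length(stats@spikeTimes) == 0L
  if (silent) {
    if (is.na(rescueSpikes))
      stop("silent cell without rescue (whole-cell current injection) info")
    label <- if (rescueSpikes > 5) "non_firing_depol_block" else "discarded"
    return(list(label = label, cv = NA_real_, controlCvMean = NA_real_,
                controlCvSd = NA_real_, threshold = NA_real_,
                reason = if (label == "discarded")
                  "silent and <=5 rescue spikes" else ""))
  }
  if (!stats@cvDefined)
    return(list(label = "discarded", cv = NA_real_,
                controlCvMean = NA_real_, controlCvSd = NA_real_,
                threshold = NA_real_,
                reason = "fewer than 3 spikes; CV undefined"))
  if (length(controlCVs) == 0L)
    stop("control group must be non-empty for firing cells")
  m <- mean(controlCVs)
  s <- stats::sd(controlCVs)
  thr <- m + s
  label <- if (stats@cv > thr) "irregular" else "regular"
  list(label = label, cv = stats@cv, controlCvMean = m, controlCvSd = s,
       threshold = thr, reason = "")
}

#' Measure the afterhyperpolarization (AHP)
#'
#' Scans current-clamp sweeps (ordered by escalating injected current) and
#' selects the first sweep whose first spike occurs within \code{maxDelayMs}
#' of the current-injection onset. The AHP is then the junction-corrected
#' membrane potential at the requested offsets after that spike's peak,
#' obtained by linear interpolation of the trace.
#'
#' @param sweeps list of current-clamp \linkS4class{TraceRecording}s, each
#'   with \code{injection_onset_s} metadata.
#' @param offsetsMs offsets after the spike peak, ms (strictly increasing;
#'   default 2.5, 5, 10, 15, 25).
#' @param maxDelayMs sweep-qualification rule: largest allowed delay from
#'   injection onset to the first spike (default 50 ms).
#' @param threshold spike-detection threshold, mV.
#' @param jp junction potential subtracted when the sweep is not already
#'   corrected, mV.
#' @return list with \code{sweepIndex}, \code{delayMs},
#'   \code{spikePeakTimeMs} (ms from injection onset), \code{offsets} and
#'   \code{potentials} (corrected mV).
#' @export
measureAHP <- function(sweeps, offsetsMs = c(2.5, 5, 10, 15, 25),
                       maxDelayMs = 50, threshold = -20, jp = 10) {
  stopifnot(is.list(sweeps), length(sweeps) >= 1L)
  if (length(offsetsMs) && any(diff(offsetsMs) <= 0))
    stop("offsets must be strictly increasing")
  for (s in seq_along(sweeps)) {
    sw <- sweeps[[s]]
    onset <- sw@metadata$injection_onset_s
    if (is.null(onset)) stop("sweep ", s, " missing 'injection_onset_s'")
    det <- detectSpikes(sw, threshold = threshold)
    post <- det$peakTimes[det$times >= onset]
    if (!length(post)) next
    firstCross <- det$times[det$times >= onset][1L]
    delay <- (firstCross - onset) * 1000
    if (delay > maxDelayMs) next
    peakT <- post[1L]
    corrected <- isTRUE(sw@metadata$junction_corrected)
    pots <- if (length(offsetsMs))
      stats::approx(sw@time, sw@signal, xout = peakT + offsetsMs / 1000)$y
    else numeric(0)
    if (!corrected) pots <- pots - jp
    return(list(sweepIndex = s, delayMs = delay,
                spikePeakTimeMs = (peakT - onset) * 1000,
                offsets = offsetsMs, potentials = pots))
  }
  stop("no sweep has a first spike within ", maxDelayMs,
       " ms of current-injection onset")
}
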