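#' Analytic inverse of the two-compartment circuit equations
#'
#' Given the circuit parameters of the reduced two-compartment neuron model,
#' returns the double-exponential transient parameters (amplitudes in pA,
#' time constants in ms) that the compartment equations map back onto the
#' circuit. Used by the synthetic transient generator and as the round-trip
#' oracle for \code{\link{compartmentParams}}:
#' A2 = dV/(R1+R2), A1 = dV/R1 - A2, tau2 = C2 (R1+R2),
#' tau1 = C1 A1 dV / (A1+A2)^2.
#'
#' @param c1,c2 capacitances, pF.
#' @param r1,r2 resistances, MOhm.
#' @param deltaV voltage-step amplitude, mV (nonzero).
#' @return list with \code{a1}, \code{a2} (pA), \code{tau1}, \code{tau2}
#'   (ms).
#' @export
twoCompartmentInverse <- function(c1, c2, r1, r2, deltaV) {
  if (r1 == 0 || r1 + r2 == 0) stop("r1 and r1 + r2 must be nonzero")
  if (deltaV == 0) stop("deltaV must be nonzero")
  # mV / MOhm = nA; express amplitudes in pA
  a2 <- 1000 * deltaV / (r1 + r2)
  a1 <- 1000 * deltaV / r1 - a2
  # pF * MOhm = us; express time constants in ms
  tau2 <- c2 * (r1 + r2) / 1000
  tau1 <- c1 * a1 * deltaV / (a1 + a2)^2
  list(a1 = a1, tau1 = tau1, a2 = a2, tau2 = tau2)
}

#' Two-compartment circuit parameters from a transient fit
#'
#' Maps the double-exponential decay parameters of a capacitative transient
#' onto the two-compartment equivalent circuit of a Purkinje neuron:
#' C1 = tau1 (A1+A2)^2 / (A1 dV) is the capacitance of the soma and main
#' proximal dendrites, C2 = A2 tau2 / dV the distal dendritic arbor,
#' R1 = dV/(A1+A2) the pipette access plus proximal internal resistance and
#' R2 = dV/A2 - dV/(A1+A2) the composite internal resistance separating the
#' distal arbor. Total capacitance is reported as |C1 + C2|. With
#' amplitudes in pA, time constants in ms and the step in mV, pA ms / mV is
#' already pF; mV/pA is GOhm and is converted to MOhm.
#'
#' @param fit a \linkS4class{TwoExponentialFit}.
#' @return a \linkS4class{TwoCompartmentEstimate}.
#' @export
compartmentParams <- function(fit) {
  stopifnot(methods::is(fit, "TwoExponentialFit"))
  if (fit@degenerate)
    stop("degenerate fit (time constants not separable); ",
         "compartment parameters are not identifiable")
  a1 <- fit@a1; a2 <- fit@a2; dv <- fit@deltaV
  if (dv == 0) stop("zero denominator: deltaV")
  if (a1 == 0) stop("zero denominator: A1")
  if (a2 == 0) stop("zero denominator: A2")
  if (a1 + a2 == 0) stop("zero denominator: A1 + A2")
  c1 <- fit@tau1 * (a1 + a2)^2 / (a1 * dv)
  c2 <- a2 * fit@tau2 / dv
  r1 <- 1000 * dv / (a1 + a2)
  r2 <- 1000 * (dv / a2 - dv / (a1 + a2))
  methods::new("TwoCompartmentEstimate", c1 = c1, c2 = c2, r1 = r1, r2 = r2,
               cTotal = abs(c1 + c2))
}

#' Average repeated voltage-step sweeps and low-pass filter
#'
#' Pointwise mean over sweeps recorded on an identical time base, followed
#' by a zero-phase (forward-backward) 4-pole Butterworth low-pass at the
#' configured cutoff (default 5 kHz, the standard conditioning for
#' capacitative transients digitized at 100 kHz).
#'
#' @param transients list of \linkS4class{TraceRecording} objects.
#' @param cutoffHz low-pass cutoff; NA skips filtering.
#' @return a \linkS4class{TraceRecording} carrying the first sweep's
#'   metadata plus \code{n_sweeps_averaged} and \code{lowpass_hz}.
#' @export
averageSweeps <- function(transients, cutoffHz = 5000) {
  stopifnot(is.list(transients), length(transients) >= 1L)
  t0 <- transients[[1L]]
  for (tr in transients[-1L]) {
    if (length(tr@time) != length(t0@time) ||
        max(abs(tr@time - t0@time)) > 1e-12 + 1e-9 * max(abs(t0@time)))
      stop("mismatched time bases across sweeps")
  }
  avg <- rowMeans(vapply(transients, methods::slot, numeric(length(t0@time)),
                         "signal"))
  if (!is.na(cutoffHz)) {
    w <- cutoffHz / (t0@samplingRate / 2)
    if (w >= 1) {
      warning("low-pass cutoff at or above Nyquist; filtering skipped")
    } else {
      bf <- signal::butter(4, w, type = "low")
      avg <- signal::filtfilt(bf, avg)
    }
  }
  meta <- t0@metadata
  meta$n_sweeps_averaged <- length(transients)
  meta$lowpass_hz <- cutoffHz
  methods::new("TraceRecording", time = t0@time, signal = avg,
               mode = t0@mode, samplingRate = t0@samplingRate,
               metadata = meta)
}

# exponential peeling on (t_ms, resid): tail gives the slow component,
# the corrected head gives the fast one. Peeling windows are scaled to the
# transient's effective support (where the smoothed decay still stands above
# a few percent of its initial size), so a long steady-state tail of pure
# noise cannot drag the slow-component estimate away.
.peelInit <- function(tms, resid) {
  n <- length(tms)
  sgn <- sign(stats::median(resid[seq_len(max(3L, n %/% 50))]))
  if (sgn == 0) sgn <- 1
  k <- max(1L, min(51L, n %/% 20))
  sm <- stats::filter(sgn * resid, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- 0
  peak <- max(sm)
  if (peak <= 0) return(NULL)
  supp <- which(sm > 0.02 * peak)
  if (!length(supp)) return(NULL)
  iSupp <- max(supp)
  safeFit <- function(ix, r) {
    ok <- ix[sgn * r[ix] > 0]
    if (length(ok) < 5L) return(NULL)
    fit <- stats::lm.fit(cbind(1, tms[ok]), log(sgn * r[ok]))
    b <- unname(fit$coefficients)
    if (!is.finite(b[2L]) || b[2L] >= 0) return(NULL)
    list(a = sgn * exp(b[1L]), tau = -1 / b[2L])
  }
  tailIx <- seq.int(max(1L, floor(iSupp * 0.35)), iSupp)
  slow <- safeFit(tailIx, resid)
  if (is.null(slow)) return(NULL)
  if (slow$tau > 3 * (tms[iSupp] - tms[1L])) return(NULL)
  headResid <- resid - slow$a * exp(-tms / slow$tau)
  headIx <- seq_len(max(5L, floor(iSupp * 0.08)))
  fast <- safeFit(headIx, headResid)
  if (is.null(fast))
    fast <- list(a = resid[1L] - slow$a, tau = slow$tau / 10)
  list(a1 = fast$a, tau1 = min(max(fast$tau, slow$tau / 200),
                               slow$tau * 0.9),
       a2 = slow$a, tau2 = slow$tau)
}

#' Fit a double-exponential decay to a capacitative transient
#'
#' Least-squares fit of i(t) = iSS + A1 exp(-t/tau1) + A2 exp(-t/tau2),
#' with t measured from the voltage-step onset (metadata
#' \code{step_onset_s}, default 0). Initialization is by exponential
#' peeling (tail fit on log residuals for the slow component, then head fit
#' for the fast one) followed by joint Levenberg-Marquardt refinement, with
#' multi-start over perturbed initializations before declaring
#' non-convergence. The first \code{blankMs} after step onset is excluded
#' (electrode artifact). Time constants are relabeled post fit so that
#' tau1 < tau2. When the two time constants collapse within
#' \code{degenerateTol} (or one amplitude is negligible) the fit is flagged
#' degenerate and a single-exponential fallback is reported in the
#' diagnostics, never silently substituted.
#'
#' @param transient a voltage-clamp \linkS4class{TraceRecording} with
#'   \code{step_mV} and \code{holding_mV} metadata.
#' @param window c(start, end) fit window in seconds on the trace's time
#'   axis; default from end of artifact blank to end of trace.
#' @param blankMs artifact blank after step onset, ms (default 0.1).
#' @param degenerateTol flag the fit degenerate when
#'   tau2/tau1 < 1 + degenerateTol (default 0.2) or
#'   min|A| < 1e-3 max|A|.
#' @param nStarts number of perturbed restarts (default 5).
#' @return a \linkS4class{TwoExponentialFit}.
#' @export
fitTwoExponential <- function(transient, window = NULL, blankMs = 0.1,
                              degenerateTol = 0.2, nStarts = 5L) {
  stopifnot(methods::is(transient, "TraceRecording"))
  if (transient@mode != "voltage_clamp")
    stop("capacitative transient fitting requires a voltage-clamp trace")
  meta <- transient@metadata
  for (k in c("step_mV", "holding_mV"))
    if (is.null(meta[[k]])) stop("transient metadata missing '", k, "'")
  deltaV <- meta$step_mV - meta$holding_mV
  if (deltaV == 0) stop("zero voltage step")
  onset <- if (is.null(meta$step_onset_s)) 0 else meta$step_onset_s
  if (is.null(window))
    window <- c(onset + blankMs / 1000, max(transient@time))
  sel <- transient@time >= window[1L] & transient@time <= window[2L]
  if (sum(sel) < 20L) stop("fit window contains too few samples")
  tms <- (transient@time[sel] - onset) * 1000
  i <- transient@signal[sel]

  issInit <- mean(i[tms >= stats::quantile(tms, 0.9)])
  generic <- list(a1 = (i[1L] - issInit) / 2, tau1 = diff(range(tms)) / 200,
                  a2 = (i[1L] - issInit) / 2, tau2 = diff(range(tms)) / 20)
  init <- .peelInit(tms, i - issInit)
  if (is.null(init)) init <- generic

  df <- data.frame(t = tms, i = i)
  best <- NULL
  tried <- 0L
  perturb <- list(c(1, 1), c(0.5, 1), c(2, 1), c(1, 0.5), c(1, 2),
                  c(0.3, 3), c(3, 0.3))
  nTry <- min(nStarts, length(perturb)) + 1L
  for (s in seq_len(nTry)) {
    base <- if (s == nTry) generic else init
    fac <- perturb[[min(s, length(perturb))]]
    if (s == nTry) fac <- c(1, 1)
    start <- list(iss = issInit, a1 = base$a1, lt1 = log(base$tau1 * fac[1L]),
                  a2 = base$a2, lt2 = log(base$tau2 * fac[2L]))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        i ~ iss + a1 * exp(-t / exp(lt1)) + a2 * exp(-t / exp(lt2)),
        data = df, start = start,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    tried <- tried + 1L
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
    if (!is.null(best) && s >= 1L && best$rss < 1e-16 * sum(i^2)) break
  }
  if (is.null(best))
    stop("double-exponential fit failed to converge after ", tried,
         " start(s)")
  cf <- stats::coef(best$fit)
  a <- c(cf[["a1"]], cf[["a2"]])
  tau <- exp(c(cf[["lt1"]], cf[["lt2"]]))
  ord <- order(tau)
  a <- a[ord]; tau <- tau[ord]

  degenerate <- (tau[2L] / tau[1L] < 1 + degenerateTol) ||
    (min(abs(a)) < 1e-3 * max(abs(a)))
  diagnostics <- list(starts_tried = tried,
                      iterations = best$fit$convInfo$finIter,
                      blank_ms = blankMs, window_s = window)
  if (degenerate) {
    sfit <- tryCatch(
      minpack.lm::nlsLM(i ~ iss + a1 * exp(-t / exp(lt1)), data = df,
                        start = list(iss = issInit, a1 = sum(a),
                                     lt1 = log(max(tau)))),
      error = function(e) NULL)
    if (!is.null(sfit)) {
      sc <- stats::coef(sfit)
      diagnostics$single_exponential <- list(
        iss = sc[["iss"]], a = sc[["a1"]], tau = exp(sc[["lt1"]]),
        rss = sum(stats::residuals(sfit)^2))
    }
  }
  methods::new("TwoExponentialFit", a1 = a[1L], tau1 = tau[1L], a2 = a[2L],
               tau2 = tau[2L], iSS = cf[["iss"]], deltaV = deltaV,
               rss = best$rss, converged = TRUE, degenerate = degenerate,
               diagnostics = diagnostics)
}

#' Capacitance from the area under the capacitative transient
#'
#' Independent capacitance estimate used as an internal-consistency check on
#' the two-compartment model: C = integral of (i(t) - iSS) dt / dV by
#' trapezoidal integration over the window, with iSS taken as the mean of
#' the final 10 percent of the window. pA s / mV is nF, converted to pF.
#' Warns when the window looks shorter than five slow time constants
#' (truncation bias).
#'
#' Unlike the double-exponential fit, integration starts at the step onset
#' by default (\code{blankMs = 0}): the area lost to an artifact blank is
#' not recoverable by the integral, whereas the fit extrapolates through
#' the blank.
#'
#' @param transient voltage-clamp \linkS4class{TraceRecording}.
#' @param window c(start, end) seconds; default from onset + blank to the
#'   end of the trace.
#' @param blankMs artifact blank, ms (default 0).
#' @return capacitance in pF.
#' @export
capacitanceAreaMethod <- function(transient, window = NULL, blankMs = 0) {
  stopifnot(methods::is(transient, "TraceRecording"))
  meta <- transient@metadata
  for (k in c("step_mV", "holding_mV"))
    if (is.null(meta[[k]])) stop("transient metadata missing '", k, "'")
  deltaV <- meta$step_mV - meta$holding_mV
  if (deltaV == 0) stop("zero voltage step")
  onset <- if (is.null(meta$step_onset_s)) 0 else meta$step_onset_s
  if (is.null(window))
    window <- c(onset + blankMs / 1000, max(transient@time))
  sel <- transient@time >= window[1L] & transient@time <= window[2L]
  tsec <- transient@time[sel] - onset
  i <- transient@signal[sel]
  iss <- mean(i[tsec >= stats::quantile(tsec, 0.9)])
  resid <- i - iss
  # slow-tau estimate (exponential peeling) drives the truncation check
  peel <- .peelInit(tsec * 1000, resid)
  if (!is.null(peel) && diff(range(tsec)) * 1000 < 5 * peel$tau2)
    warning("integration window shorter than ~5 slow time constants; ",
            "area-method capacitance may be truncation-biased")
  1000 * pracma::trapz(tsec, resid) / deltaV
}

#' Recording quality control
#'
#' Applies the standard whole-cell QC rules: reject when series resistance
#' rises above the absolute limit (default 15 MOhm), when it changes by more
#' than the configured fraction of its initial value (default 20 percent),
#' and -- for the capacitance protocol -- when input resistance is below the
#' floor (default 100 MOhm). Missing fields fail with reason "missing".
#'
#' @param meta named list with \code{series_r_start_MOhm},
#'   \code{series_r_end_MOhm} and (when \code{checkInputR}) \code{input_r_MOhm}.
#' @param maxSeriesR absolute series-resistance limit, MOhm.
#' @param maxSeriesChangePct maximal percent change relative to the initial
#'   value.
#' @param minInputR input-resistance floor, MOhm.
#' @param checkInputR apply the input-resistance rule (capacitance protocol
#'   only).
#' @return list with \code{pass} (logical) and \code{reasons} (character).
#' @export
qcRecording <- function(meta, maxSeriesR = 15, maxSeriesChangePct = 20,
                        minInputR = 100, checkInputR = TRUE) {
  reasons <- character()
  rs0 <- meta$series_r_start_MOhm
  rs1 <- meta$series_r_end_MOhm
  if (is.null(rs0) || is.null(rs1)) {
    reasons <- c(reasons, "missing: series resistance")
  } else {
    if (max(rs0, rs1) > maxSeriesR)
      reasons <- c(reasons, sprintf("series resistance %.3g MOhm above %g MOhm",
                                    max(rs0, rs1), maxSeriesR))
    chg <- 100 * abs(rs1 - rs0) / rs0
    if (chg > maxSeriesChangePct)
      reasons <- c(reasons, sprintf("series resistance changed by %.3g%% (> %g%%)",
                                    chg, maxSeriesChangePct))
  }
  if (checkInputR) {
    ri <- meta$input_r_MOhm
    if (is.null(ri)) reasons <- c(reasons, "missing: input resistance")
    else if (ri < minInputR)
      reasons <- c(reasons, sprintf("input resistance %.3g MOhm below %g MOhm",
                                    ri, minInputR))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Correct voltages for the liquid junction potential
#'
#' Recorded voltages are stored uncorrected; this applies the standard
#' correction, corrected = recorded - jp (default +10 mV), exactly once.
#' For a \linkS4class{TraceRecording} the correction state is tracked by the
#' \code{junction_corrected} metadata flag and a second application is an
#' error. For a bare numeric the subtraction is returned directly (the
#' caller owns the bookkeeping).
#'
#' @param x voltage-mode \linkS4class{TraceRecording} or numeric mV.
#' @param jp junction potential, mV (default 10).
#' @return same type as \code{x}, corrected.
#' @export
correctJunctionPotential <- function(x, jp = 10) {
  if (is.numeric(x)) return(x - jp)
  stopifnot(methods::is(x, "TraceRecording"))
  if (x@mode == "voltage_clamp")
    stop("junction correction applies to recorded voltages ",
         "(current- or cell-attached traces)")
  if (isTRUE(x@metadata$junction_corrected))
    stop("trace is already junction-corrected")
  meta <- x@metadata
  meta$junction_corrected <- TRUE
  meta$junction_potential_mV <- jp
  methods::new("TraceRecording", time = x@time, signal = x@signal - jp,
               mode = x@mode, samplingRate = x@samplingRate, metadata = meta)
}
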