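#' Synthetic-study configuration
#'
#' Collects, with defaults mirroring the study conditions the pipeline is
#' designed for, every parameter of the synthetic-data generators: the
#' 270-gene channel universe; four models with a planted 12-gene
#' at-least-3-of-4 overlap of which 11 genes are consistently
#' downregulated; Purkinje-scale circuit parameters for capacitative
#' transients digitized at 100 kHz; gamma-ISI spike trains; qPCR fold
#' changes in the 0.4-0.8 range; and an 18 percent planted
#' immunofluorescence group effect.
#'
#' @param seed integer RNG seed recorded in every emitted truth manifest.
#' @param universeSize channel-universe size (default 270).
#' @param modelIds labels of the four models.
#' @param drawSizes per-model numbers of DE channel genes.
#' @param nShared number of genes planted in >= 3 of 4 models (default 12).
#' @param nSharedDown how many of those are consistently down (default 11).
#' @param circuit list: c1 (pF), c2 (pF), r1, r2 (MOhm), deltaV (mV), iSS
#'   (pA), noiseSd (pA), fs (Hz), duration (s).
#' @param spikes list: rate (Hz), cv, duration (s), silentFraction,
#'   depolBlockFraction.
#' @param qpcr list: baseCt, foldChanges (named per gene), ctNoiseSd,
#'   nPerGroup, nReplicates.
#' @param chip list: dilutionsPct, efficiency, interceptCt, plantedPct,
#'   ctNoiseSd.
#' @param intensity list: effect (fractional, default 0.18), nAnimals,
#'   cellsPerAnimal, cellNoiseSd, lineLengthUm.
#' @return list of class \code{"synthConfig"}.
#' @export
synthConfig <- function(seed = 1L,
                        universeSize = 270L,
                        modelIds = c("ATXN1[82Q]", "Atxn1-154Q/2Q",
                                     "ATXN2[Q127]", "ATXN2-BAC-Q72"),
                        drawSizes = c(30L, 42L, 25L, 36L),
                        nShared = 12L, nSharedDown = 11L,
                        circuit = list(c1 = 15, c2 = 450, r1 = 8, r2 = 10,
                                       deltaV = -10, iSS = -100,
                                       noiseSd = 10, fs = 1e5,
                                       duration = 1),
                        spikes = list(rate = 60, cv = 0.06, duration = 10,
                                      silentFraction = 0.1,
                                      depolBlockFraction = 0.8),
                        qpcr = list(baseCt = 22,
                                    foldChanges = c(Kcnma1 = 0.45,
                                                    Cacna1g = 0.55,
                                                    Itpr1 = 0.7,
                                                    Trpc3 = 0.65),
                                    ctNoiseSd = 0.15, nPerGroup = 6L,
                                    nReplicates = 3L),
                        chip = list(dilutionsPct = c(2, 0.2, 0.02),
                                    efficiency = 1, interceptCt = 26,
                                    plantedPct = c(0.8, 0.25, 0.05),
                                    ctNoiseSd = 0.1),
                        intensity = list(effect = 0.18, nAnimals = 5L,
                                         cellsPerAnimal = 6L,
                                         cellNoiseSd = 0.08,
                                         lineLengthUm = 15)) {
  cfg <- list(seed = as.integer(seed), universeSize = as.integer(universeSize),
              modelIds = modelIds, drawSizes = as.integer(drawSizes),
              nShared = as.integer(nShared),
              nSharedDown = as.integer(nSharedDown), circuit = circuit,
              spikes = spikes, qpcr = qpcr, chip = chip,
              intensity = intensity)
  if (length(cfg$drawSizes) != length(cfg$modelIds))
    stop("drawSizes must match modelIds")
  if (any(cfg$drawSizes > cfg$universeSize))
    stop("draw sizes cannot exceed the universe size")
  if (cfg$nShared > min(sort(cfg$drawSizes, decreasing = TRUE)[1:3]))
    stop("infeasible plan: planted shared genes exceed model capacity")
  if (cfg$nSharedDown > cfg$nShared)
    stop("nSharedDown cannot exceed nShared")
  if (cfg$intensity$effect < 0) stop("intensity effect must be >= 0")
  class(cfg) <- "synthConfig"
  cfg
}

#' Synthetic channel universe
#'
#' A generated universe of the configured size: the bundled curated channel
#' list when its size matches (the default 270), otherwise symbols
#' \code{Chnl001 ...}.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @return a \linkS4class{ChannelUniverse}.
#' @export
genUniverse <- function(cfg) {
  fixture <- channelUniverseFixture()
  genes <- normalizeGeneSymbols(grep("^\\s*(#|$)",
                                     readLines(fixture, warn = FALSE),
                                     value = TRUE, invert = TRUE))
  if (cfg$universeSize == length(genes))
    methods::new("ChannelUniverse", genes = genes,
                 label = "curated synthetic snapshot")
  else
    methods::new("ChannelUniverse",
                 genes = sprintf("Chnl%03d", seq_len(cfg$universeSize)),
                 label = "generated")
}

#' Generate per-model DE tables with a planted cross-model overlap
#'
#' Builds one DE table per model. The planted shared genes are assigned to
#' 3 or 4 of the models so that exactly \code{nShared} genes sit in the
#' at-least-3-of-4 union, \code{nSharedDown} of them consistently
#' downregulated. Each model's remaining quota is filled with channel genes
#' constrained to at most two models (so fillers never contaminate the
#' >=3 union), and non-channel decoy genes (both DE and non-DE) are mixed
#' in to exercise the universe filter.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @param universe optional \linkS4class{ChannelUniverse} (default
#'   \code{genUniverse(cfg)}).
#' @return list with \code{tables} (named list of DE data.frames) and
#'   \code{truth} (planted genes, their model membership and directions,
#'   the expected >=3-of-4 union and consistent-down set, draw sizes,
#'   seed).
#' @export
genDETables <- function(cfg, universe = genUniverse(cfg)) {
  stopifnot(inherits(cfg, "synthConfig"))
  nModels <- length(cfg$modelIds)
  .withSeed(cfg$seed, {
    genes <- universeGenes(universe)
    shared <- sample(genes, cfg$nShared)
    membership <- lapply(seq_len(cfg$nShared), function(i)
      sort(sample.int(nModels, sample(c(3L, nModels), 1L))))
    names(membership) <- shared
    dirShared <- c(rep("down", cfg$nSharedDown),
                   rep("up", cfg$nShared - cfg$nSharedDown))
    names(dirShared) <- shared

    pool <- setdiff(genes, shared)
    fillerUse <- stats::setNames(integer(length(pool)), pool)
    modelGenes <- vector("list", nModels)
    for (m in seq_len(nModels)) {
      planted <- shared[vapply(membership, function(mm) m %in% mm,
                               logical(1))]
      need <- cfg$drawSizes[m] - length(planted)
      if (need < 0L) stop("infeasible plan for model ", cfg$modelIds[m])
      avail <- names(fillerUse)[fillerUse < 2L]
      fill <- sample(avail, need)
      fillerUse[fill] <- fillerUse[fill] + 1L
      modelGenes[[m]] <- c(planted, fill)
    }

    tables <- lapply(seq_len(nModels), function(m) {
      gs <- modelGenes[[m]]
      lfc <- numeric(length(gs))
      isShared <- gs %in% shared
      down <- isShared & dirShared[gs] == "down"
      # planted folds ~0.4-0.8 (log2 about -1.3 to -0.3); up-genes mirrored
      lfc[down] <- log2(stats::runif(sum(down), 0.4, 0.8))
      lfc[isShared & !down] <- -log2(stats::runif(sum(isShared & !down),
                                                  0.4, 0.8))
      lfc[!isShared] <- sample(c(-1, 1), sum(!isShared), replace = TRUE) *
        stats::runif(sum(!isShared), 0.3, 1.5)
      de <- data.frame(gene = gs, log2fc = lfc,
                       padj = stats::runif(length(gs), 1e-8, 0.005),
                       is_de = TRUE, stringsAsFactors = FALSE)
      nDecoy <- 200L
      decoys <- data.frame(
        gene = sprintf("Decoy%04d", sample.int(5000L, nDecoy)),
        log2fc = stats::rnorm(nDecoy, 0, 1),
        padj = stats::runif(nDecoy, 0, 1),
        stringsAsFactors = FALSE)
      decoys <- decoys[!duplicated(decoys$gene), ]
      decoys$is_de <- decoys$padj < 0.01
      out <- rbind(de, decoys)
      out[sample.int(nrow(out)), ]
    })
    names(tables) <- cfg$modelIds

    counts <- table(unlist(lapply(membership, identity)))
    degree <- vapply(shared, function(g) length(membership[[g]]), integer(1))
    list(tables = tables,
         truth = list(seed = cfg$seed,
                      plantedGenes = shared,
                      membership = membership,
                      directions = dirShared,
                      atLeast3 = sort(shared[degree >= 3L]),
                      consistentDown = sort(shared[dirShared == "down"]),
                      drawSizes = cfg$drawSizes,
                      universeSize = length(genes)))
  })
}

#' Generate a synthetic capacitative transient from circuit ground truth
#'
#' Forward-simulates the double-exponential transient of a two-compartment
#' cell via the analytic inverse of the compartment equations, adds
#' Gaussian current noise, and packages the result as a voltage-clamp
#' \linkS4class{TraceRecording} (holding -80 mV, step to -90 mV by
#' default) together with the ground-truth manifest.
#'
#' @param c1,c2 pF; \code{r1,r2} MOhm; \code{deltaV} mV; \code{iSS} pA.
#' @param r1,r2,deltaV,iSS circuit parameters (see above).
#' @param noiseSd Gaussian current noise SD, pA.
#' @param fs sampling rate, Hz (default 100 kHz).
#' @param duration trace length, s.
#' @param seed RNG seed (only used when noiseSd > 0).
#' @param holding holding potential, mV.
#' @return list with \code{trace} and \code{truth} (circuit and transient
#'   parameters).
#' @export
genTransient <- function(c1, c2, r1, r2, deltaV = -10, iSS = -100,
                         noiseSd = 0, fs = 1e5, duration = 1,
                         seed = 1L, holding = -80) {
  par <- twoCompartmentInverse(c1, c2, r1, r2, deltaV)
  time <- seq(0, duration, by = 1 / fs)
  tms <- time * 1000
  clean <- iSS + par$a1 * exp(-tms / par$tau1) + par$a2 * exp(-tms / par$tau2)
  sig <- if (noiseSd > 0)
    .withSeed(seed, clean + stats::rnorm(length(clean), 0, noiseSd))
  else clean
  trace <- methods::new(
    "TraceRecording", time = time, signal = sig, mode = "voltage_clamp",
    samplingRate = fs,
    metadata = list(holding_mV = holding, step_mV = holding + deltaV,
                    step_onset_s = 0, series_r_start_MOhm = r1,
                    series_r_end_MOhm = r1, input_r_MOhm = 150,
                    sweep_index = 1L))
  list(trace = trace,
       truth = list(c1 = c1, c2 = c2, r1 = r1, r2 = r2, deltaV = deltaV,
                    iSS = iSS, a1 = par$a1, tau1 = par$tau1, a2 = par$a2,
                    tau2 = par$tau2, noiseSd = noiseSd, seed = seed))
}

#' Generate a gamma-ISI spike train with target rate and CV
#'
#' Interspike intervals are gamma distributed with shape 1/CV^2 and scale
#' CV^2/rate, so the mean ISI is 1/rate and the ISI coefficient of
#' variation equals the target up to sampling error. CV -> 0 approaches a
#' periodic train.
#'
#' @param rate mean firing rate, Hz (> 0).
#' @param cvTarget target ISI CV (> 0).
#' @param duration train length, s.
#' @param seed RNG seed.
#' @return numeric vector of spike times in (0, duration).
#' @export
genSpikeTrain <- function(rate, cvTarget, duration, seed = 1L) {
  if (rate <= 0 || cvTarget <= 0) stop("rate and cvTarget must be positive")
  shape <- 1 / cvTarget^2
  scale <- cvTarget^2 / rate
  .withSeed(seed, {
    n <- max(10L, ceiling(rate * duration * 2 + 10 * sqrt(rate * duration)))
    isi <- stats::rgamma(n, shape = shape, scale = scale)
    times <- cumsum(isi)
    while (times[length(times)] < duration) {
      isi <- stats::rgamma(n, shape = shape, scale = scale)
      times <- c(times, times[length(times)] + cumsum(isi))
    }
    times <- times[times < duration]
    if (length(times) < 3L)
      stop("duration too short to realize at least 3 spikes")
    times
  })
}

# post-peak AHP waveform: brief triangular spike repolarization followed by
# an exponential recovery from the trough toward baseline
.ahpWaveform <- function(dtMs, peakMv, baseMv, troughMv, tauMs,
                         spikeHalfMs = 0.5) {
  ifelse(dtMs <= spikeHalfMs,
         peakMv + (troughMv - peakMv) * dtMs / spikeHalfMs,
         baseMv + (troughMv - baseMv) * exp(-(dtMs - spikeHalfMs) / tauMs))
}

#' Generate escalating-current AHP sweeps with known ground truth
#'
#' Builds a current-clamp sweep per requested first-spike delay: baseline
#' at \code{baseMv} (uncorrected scale), one stereotyped spike whose peak
#' sits \code{delay} after the injection onset, then a parametric
#' afterhyperpolarization (exponential recovery from a trough). The truth
#' manifest carries the closed-form uncorrected and junction-corrected
#' potentials at the requested offsets.
#'
#' @param delaysMs first-spike delays from injection onset, one sweep each.
#' @param offsetsMs offsets after the spike peak at which truth potentials
#'   are tabulated.
#' @param fs sampling rate, Hz.
#' @param baseMv resting/baseline potential, mV (uncorrected).
#' @param peakMv spike peak, mV.
#' @param troughMv AHP trough, mV.
#' @param tauMs AHP recovery time constant, ms.
#' @param jp junction potential used for the corrected truth values.
#' @return list with \code{sweeps} (list of \linkS4class{TraceRecording})
#'   and \code{truth} (qualifying sweep, per-offset potentials).
#' @export
genAHPSweeps <- function(delaysMs, offsetsMs = c(2.5, 5, 10, 15, 25),
                         fs = 5e4, baseMv = -70, peakMv = 30,
                         troughMv = -78, tauMs = 30, jp = 10) {
  if (!length(delaysMs)) stop("need at least one sweep delay")
  onset <- 0.1
  dur <- onset + max(delaysMs) / 1000 + 0.2
  time <- seq(0, dur, by = 1 / fs)
  spikeRiseMs <- 0.5
  sweeps <- lapply(seq_along(delaysMs), function(s) {
    d <- delaysMs[s]
    peakT <- onset + d / 1000
    v <- rep(baseMv, length(time))
    rel <- (time - peakT) * 1000
    rise <- rel >= -spikeRiseMs & rel < 0
    v[rise] <- baseMv + (peakMv - baseMv) * (rel[rise] + spikeRiseMs) / spikeRiseMs
    post <- rel >= 0
    v[post] <- .ahpWaveform(rel[post], peakMv, baseMv, troughMv, tauMs)
    methods::new("TraceRecording", time = time, signal = v,
                 mode = "current_clamp", samplingRate = fs,
                 metadata = list(injection_onset_s = onset,
                                 sweep_index = s,
                                 junction_corrected = FALSE))
  })
  qualifying <- which(delaysMs <= 50)[1L]
  pots <- .ahpWaveform(offsetsMs, peakMv, baseMv, troughMv, tauMs)
  list(sweeps = sweeps,
       truth = list(delaysMs = delaysMs, qualifyingSweep = qualifying,
                    offsetsMs = offsetsMs, potentialsUncorrected = pots,
                    potentialsCorrected = pots - jp, jp = jp,
                    baseMv = baseMv, troughMv = troughMv, tauMs = tauMs))
}

#' Generate qPCR Ct tables with planted fold changes
#'
#' Cts follow base - log2(relative quantity) + noise; the reference gene's
#' relative quantity is 1 everywhere, target genes carry the planted fold
#' in the affected group and 1 in the calibrator group.
#'
#' @param cfg a \code{\link{synthConfig}} (fields under \code{qpcr}).
#' @param groups two group labels, calibrator first.
#' @return list with \code{cts} (long data.frame: gene, sample_id, group,
#'   ct) and \code{truth} (planted folds, noise SD, seed).
#' @export
genCtTables <- function(cfg, groups = c("WT", "ATXN1[82Q]")) {
  stopifnot(inherits(cfg, "synthConfig"), length(groups) == 2L)
  q <- cfg$qpcr
  .withSeed(cfg$seed + 1L, {
    rows <- list()
    for (g in seq_along(groups)) {
      for (s in seq_len(q$nPerGroup)) {
        sid <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", groups[g]), s)
        # reference gene (Actb): relative quantity 1 in every sample
        rows[[length(rows) + 1L]] <- data.frame(
          gene = "Actb", sample_id = sid, group = groups[g],
          ct = 18 + stats::rnorm(q$nReplicates, 0, q$ctNoiseSd))
        for (gene in names(q$foldChanges)) {
          rel <- if (g == 1L) 1 else q$foldChanges[[gene]]
          rows[[length(rows) + 1L]] <- data.frame(
            gene = gene, sample_id = sid, group = groups[g],
            ct = q$baseCt - log2(rel) +
              stats::rnorm(q$nReplicates, 0, q$ctNoiseSd))
        }
      }
    }
    list(cts = do.call(rbind, rows),
         truth = list(foldChanges = q$foldChanges, calibrator = groups[1L],
                      ctNoiseSd = q$ctNoiseSd, seed = cfg$seed + 1L))
  })
}

#' Generate a ChIP-qPCR input dilution series and ChIP sample Cts
#'
#' The standard curve follows Ct = intercept + slope log10(percent input)
#' with slope = -1/log10(1 + efficiency); ChIP samples are placed at the
#' planted percent-input values, with Ct noise.
#'
#' @param cfg a \code{\link{synthConfig}} (fields under \code{chip}).
#' @return list with \code{standards} (percent, ct), \code{samples}
#'   (sample_id, ct) and \code{truth} (planted percents, slope, intercept).
#' @export
genChip <- function(cfg) {
  stopifnot(inherits(cfg, "synthConfig"))
  ch <- cfg$chip
  slope <- -1 / log10(1 + ch$efficiency)
  .withSeed(cfg$seed + 2L, {
    standards <- data.frame(
      percent = ch$dilutionsPct,
      ct = ch$interceptCt + slope * log10(ch$dilutionsPct))
    samples <- data.frame(
      sample_id = sprintf("chip_%02d", seq_along(ch$plantedPct)),
      ct = ch$interceptCt + slope * log10(ch$plantedPct) +
        stats::rnorm(length(ch$plantedPct), 0, ch$ctNoiseSd))
    list(standards = standards, samples = samples,
         truth = list(plantedPct = ch$plantedPct, slope = slope,
                      intercept = ch$interceptCt,
                      efficiency = ch$efficiency, seed = cfg$seed + 2L))
  })
}

#' Generate somatic line-profile intensity tables with a planted effect
#'
#' Per-cell Gaussian-bump intensity profiles across the soma, with
#' per-animal and per-cell lognormal variation. The affected group
#' (mutant anterior cerebellum) carries a planted fractional increase
#' (default 18 percent) in mean profile height over the reference group.
#'
#' @param cfg a \code{\link{synthConfig}} (fields under \code{intensity}).
#' @param groups group labels; the first is the reference (wild-type
#'   anterior), the second the affected group.
#' @return list with \code{profiles} (named list of data.frames with
#'   columns \code{position_um}, \code{intensity}), \code{cells}
#'   (data.frame: cell_id, animal, group) and \code{truth}.
#' @export
genProfiles <- function(cfg, groups = c("WT_anterior", "82Q_anterior")) {
  stopifnot(inherits(cfg, "synthConfig"), length(groups) == 2L)
  it <- cfg$intensity
  .withSeed(cfg$seed + 3L, {
    profiles <- list()
    cells <- list()
    pos <- seq(0, it$lineLengthUm, length.out = 40L)
    for (g in seq_along(groups)) {
      scaleG <- if (g == 1L) 1 else 1 + it$effect
      for (a in seq_len(it$nAnimals)) {
        animal <- sprintf("%s_a%02d", groups[g], a)
        animalScale <- exp(stats::rnorm(1, 0, 0.03))
        for (cix in seq_len(it$cellsPerAnimal)) {
          cellId <- sprintf("%s_c%02d", animal, cix)
          amp <- 100 * scaleG * animalScale *
            exp(stats::rnorm(1, 0, it$cellNoiseSd))
          mid <- it$lineLengthUm / 2
          width <- it$lineLengthUm / 5
          intensity <- amp * exp(-(pos - mid)^2 / (2 * width^2)) +
            stats::rnorm(length(pos), 0, 0.5)
          profiles[[cellId]] <- data.frame(position_um = pos,
                                           intensity = intensity)
          cells[[length(cells) + 1L]] <- data.frame(
            cell_id = cellId, animal = animal, group = groups[g],
            stringsAsFactors = FALSE)
        }
      }
    }
    list(profiles = profiles, cells = do.call(rbind, cells),
         truth = list(effect = it$effect, referenceGroup = groups[1L],
                      affectedGroup = groups[2L], seed = cfg$seed + 3L))
  })
}

#' Generate a synthetic three-contrast triple with planted dependence
#' categories
#'
#' Plants genes in each ATXN1-Cic dependence category with effects that
#' clear the DE threshold by construction: dependent genes are DE in the
#' 82Q-vs-WT and mutant-vs-82Q contrasts only; partially dependent genes
#' are DE in all three; independent genes are not DE in mutant-vs-82Q.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @param nDependent,nPartial,nIndependent planted category sizes.
#' @return list with \code{triple} (a \code{\link{contrastTriple}}) and
#'   \code{truth} (gene -> category and direction).
#' @export
genContrastTriple <- function(cfg, nDependent = 6L, nPartial = 4L,
                              nIndependent = 8L) {
  stopifnot(inherits(cfg, "synthConfig"))
  .withSeed(cfg$seed + 4L, {
    universe <- genUniverse(cfg)
    total <- nDependent + nPartial + nIndependent
    genes <- sample(universeGenes(universe), total)
    category <- rep(c("dependent", "partially_dependent", "independent"),
                    c(nDependent, nPartial, nIndependent))
    dirDown <- stats::runif(total) < 0.85

    lfc82 <- ifelse(dirDown, log2(stats::runif(total, 0.4, 0.8)),
                    -log2(stats::runif(total, 0.4, 0.8)))
    de82 <- rep(TRUE, total)
    # independent genes: leave some not DE anywhere in 82Q as well
    notDe82 <- category == "independent" & stats::runif(total) < 0.4
    de82[notDe82] <- FALSE
    lfc82[notDe82] <- stats::rnorm(sum(notDe82), 0, 0.05)

    # mutant vs WT: dependent -> normalized (not DE); partial -> still DE
    deMW <- category == "partially_dependent"
    lfcMW <- ifelse(deMW, lfc82 * stats::runif(total, 0.4, 0.7),
                    stats::rnorm(total, 0, 0.05))
    # mutant vs 82Q: DE for dependent and partial (rescue), not for indep
    deM8 <- category != "independent"
    lfcM8 <- ifelse(deM8, lfcMW - lfc82, stats::rnorm(total, 0, 0.05))

    mk <- function(lfc, de) data.frame(
      gene = genes, log2fc = lfc,
      padj = ifelse(de, stats::runif(total, 1e-8, 0.005),
                    stats::runif(total, 0.2, 1)),
      is_de = de, stringsAsFactors = FALSE)
    triple <- contrastTriple(mk(lfc82, de82), mk(lfcMW, deMW),
                             mk(lfcM8, deM8), alpha = 0.01)
    list(triple = triple,
         truth = list(gene = genes, category = category,
                      direction = ifelse(!de82, "none",
                                         ifelse(dirDown, "down", "up")),
                      seed = cfg$seed + 4L))
  })
}

#' Generate a cohort of spike trains with planted firing classes
#'
#' Control cells fire regularly (low CV); test cells are a mixture of
#' regular, irregular (CV well above the control mean + SD) and silent
#' cells, silent cells carrying a rescue spike count that classifies them
#' as depolarization block (> 5) or discard (<= 5).
#'
#' @param cfg a \code{\link{synthConfig}} (fields under \code{spikes}).
#' @param nControl,nTest cohort sizes.
#' @return list with \code{controls} (list of spike-time vectors),
#'   \code{cells} (list with \code{times}, \code{rescueSpikes}) and
#'   \code{truth} (planted labels).
#' @export
genFiringCohort <- function(cfg, nControl = 10L, nTest = 12L) {
  stopifnot(inherits(cfg, "synthConfig"))
  sp <- cfg$spikes
  .withSeed(cfg$seed + 5L, {
    controls <- lapply(seq_len(nControl), function(i)
      genSpikeTrain(sp$rate, sp$cv, sp$duration,
                    seed = cfg$seed + 100L + i))
    labels <- character(nTest)
    cells <- vector("list", nTest)
    nSilent <- round(sp$silentFraction * nTest)
    for (i in seq_len(nTest)) {
      if (i <= nSilent) {
        block <- stats::runif(1) < sp$depolBlockFraction
        labels[i] <- if (block) "non_firing_depol_block" else "discarded"
        cells[[i]] <- list(times = numeric(0),
                           rescueSpikes = if (block) 12L else 3L)
      } else if (i %% 3 == 0) {
        labels[i] <- "irregular"
        cells[[i]] <- list(times = genSpikeTrain(sp$rate * 0.7, sp$cv * 6,
                                                 sp$duration,
                                                 seed = cfg$seed + 200L + i),
                           rescueSpikes = NA)
      } else {
        labels[i] <- "regular"
        cells[[i]] <- list(times = genSpikeTrain(sp$rate, sp$cv * 0.8,
                                                 sp$duration,
                                                 seed = cfg$seed + 200L + i),
                           rescueSpikes = NA)
      }
    }
    list(controls = controls, cells = cells,
         truth = list(labels = labels, seed = cfg$seed + 5L))
  })
}
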