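#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates the stages in dependency order -- synthetic-data generation,
#' cross-model channel overlap with permutation test, ATXN1-Cic dependence
#' classification, electrophysiology feature extraction, and molecular
#' quantification -- writing per-stage JSON outputs and a single
#' reproducibility manifest to \code{outDir}. Stage failures are isolated:
#' the remaining stages still run and the manifest records the partial
#' state.
#'
#' @param config a \code{\link{synthConfig}} (also carries the pipeline
#'   thresholds through its fields).
#' @param outDir output directory (created if absent).
#' @param kStar at-least-k threshold for the overlap stage (default 3).
#' @param nSims permutation simulations (default 1000).
#' @return the run manifest (list), invisibly written as
#'   \code{manifest.json}.
#' @export
runPipeline <- function(config = synthConfig(), outDir = tempfile("run"),
                        kStar = 3L, nSims = 1000L) {
  stopifnot(inherits(config, "synthConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = configHash(config), seed = config$seed,
                   package_version =
                     as.character(utils::packageVersion("ataxiaChannels")),
                   stages = list())
  runStage <- function(name, fn) {
    res <- tryCatch(list(ok = TRUE, value = fn()),
                    error = function(e) list(ok = FALSE,
                                             error = conditionMessage(e)))
    manifest$stages[[name]] <<- if (res$ok)
      list(status = "ok", outputs = res$value)
    else list(status = "failed", error = res$error)
    if (res$ok) res$value else NULL
  }

  universe <- genUniverse(config)

  overlapOut <- runStage("overlap", function() {
    de <- genDETables(config, universe)
    sets <- lapply(names(de$tables), function(m)
      filterChannels(de$tables[[m]], universe, m))
    summ <- computeOverlaps(sets, kStar = kStar)
    observed <- length(atLeastK(summ, kStar))
    perm <- permutationOverlapTest(
      drawSizes = lengths(lapply(sets, deChannels)),
      universeSize = length(universe), observed = observed,
      kStar = kStar, nSims = nSims, seed = config$seed)
    upsetPath <- file.path(outDir, "upset_counts.tsv")
    exportUpset(summ, upsetPath)
    writeResultJSON(
      list(models = summ@models,
           union_size = sum(exclusiveCounts(summ)),
           at_least_k = observed, k_star = kStar,
           consistent_down = length(consistentDown(summ)),
           genes = atLeastK(summ, kStar),
           p_value = pValue(perm), p_raw = perm@pRaw, n_ge = perm@nGe,
           n_sims = perm@nSims),
      file.path(outDir, "overlap_summary.json"), seed = config$seed,
      config = config)
    list(at_least_k = observed,
         consistent_down = length(consistentDown(summ)),
         p_value = pValue(perm), upset_table = upsetPath,
         truth_at_least_3 = length(de$truth$atLeast3))
  })

  cicOut <- runStage("cic_dependence", function() {
    gen <- genContrastTriple(config)
    calls <- classifyDependence(gen$triple)
    agree <- mean(calls$category[match(gen$truth$gene, calls$gene)] ==
                    gen$truth$category)
    panel <- log2fcPanel(gen$triple, gen$truth$gene)
    utils::write.table(calls, file.path(outDir, "dependence_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeResultJSON(
      list(n_dependent = sum(calls$category == "dependent"),
           n_partially_dependent =
             sum(calls$category == "partially_dependent"),
           n_independent = sum(calls$category == "independent"),
           truth_agreement = agree),
      file.path(outDir, "dependence_summary.json"), seed = config$seed,
      config = config)
    list(truth_agreement = agree, n_genes = nrow(calls),
         panel_genes = nrow(panel))
  })

  ephysOut <- runStage("ephys", function() {
    ci <- config$circuit
    gen <- genTransient(ci$c1, ci$c2, ci$r1, ci$r2, ci$deltaV, ci$iSS,
                        noiseSd = ci$noiseSd, fs = ci$fs,
                        duration = ci$duration, seed = config$seed)
    fit <- fitTwoExponential(gen$trace)
    est <- compartmentParams(fit)
    areaC <- suppressWarnings(capacitanceAreaMethod(gen$trace))
    cohort <- genFiringCohort(config)
    controlCVs <- vapply(cohort$controls, function(ts)
      isiCV(spikeStats(ts, config$spikes$duration)), numeric(1))
    labels <- vapply(seq_along(cohort$cells), function(i) {
      cell <- cohort$cells[[i]]
      classifyFiring(spikeStats(cell$times, config$spikes$duration),
                     controlCVs, rescueSpikes = cell$rescueSpikes)$label
    }, character(1))
    ahp <- genAHPSweeps(delaysMs = c(80, 45, 20))
    ahpRes <- measureAHP(ahp$sweeps)
    writeResultJSON(
      list(c1_pF = est@c1, c2_pF = est@c2, r1_MOhm = est@r1,
           r2_MOhm = est@r2, c_total_pF = totalCapacitance(est),
           c_area_pF = areaC,
           firing_counts = as.list(table(labels)),
           ahp_sweep = ahpRes$sweepIndex,
           ahp_potentials_mV = ahpRes$potentials),
      file.path(outDir, "ephys_summary.json"), seed = config$seed,
      config = config)
    list(c_total_pF = totalCapacitance(est), c_area_pF = areaC,
         truth_c_total = ci$c1 + ci$c2,
         firing_truth_agreement =
           mean(labels == cohort$truth$labels),
         ahp_sweep = ahpRes$sweepIndex)
  })

  quantOut <- runStage("quant", function() {
    ct <- genCtTables(config)
    folds <- ddctTable(ct$cts, referenceGene = "Actb",
                       calibratorGroup = ct$truth$calibrator)
    foldMeans <- stats::aggregate(fold ~ gene + group, data = folds,
                                  FUN = mean)
    chip <- genChip(config)
    curve <- fitStandardCurve(chip$standards$percent, chip$standards$ct)
    pct <- percentInput(chip$samples$ct, curve)
    prof <- genProfiles(config)
    scores <- do.call(rbind, lapply(prof$cells$cell_id, function(cid) {
      p <- prof$profiles[[cid]]
      data.frame(cell_id = cid, score = profileScore(p$position_um,
                                                     p$intensity)$score)
    }))
    scores <- merge(scores, prof$cells, by = "cell_id")
    norm <- normalizeScores(scores, prof$truth$referenceGroup)
    gm <- stats::aggregate(normalized ~ group, data = norm, FUN = mean)
    eff <- percentDifference(
      gm$normalized[gm$group == prof$truth$affectedGroup],
      gm$normalized[gm$group == prof$truth$referenceGroup])
    utils::write.table(folds, file.path(outDir, "qpcr_folds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeResultJSON(
      list(fold_means = stats::setNames(as.list(foldMeans$fold),
                                        paste(foldMeans$gene,
                                              foldMeans$group, sep = "|")),
           percent_input = as.list(stats::setNames(pct,
                                                   chip$samples$sample_id)),
           curve_efficiency = efficiency(curve),
           intensity_effect_pct = eff),
      file.path(outDir, "quant_summary.json"), seed = config$seed,
      config = config)
    list(intensity_effect_pct = eff,
         truth_effect_pct = 100 * prof$truth$effect,
         curve_efficiency = efficiency(curve))
  })

  outFiles <- list.files(outDir, full.names = TRUE)
  outFiles <- outFiles[basename(outFiles) != "manifest.json"]
  manifest$file_digests <- as.list(tools::md5sum(outFiles))
  names(manifest$file_digests) <- basename(outFiles)
  manifest$pass <- all(vapply(manifest$stages, function(s)
    identical(s$status, "ok"), logical(1)))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(manifest)
}

.round2 <- function(x) formatC(round(x, 2), format = "f", digits = 2)

#' Human-readable pipeline report
#'
#' Renders the manifest's stage summaries as text, with values rounded to
#' two decimal places for presentation only (full precision stays in the
#' JSON outputs). Empty or failed stages are reported with a notice rather
#' than omitted silently.
#'
#' @param manifest list as returned by \code{\link{runPipeline}}.
#' @param file optional path to also write the report to.
#' @return character vector of report lines, invisibly; printed to the
#'   console.
#' @export
pipelineReport <- function(manifest, file = NULL) {
  lines <- c("ataxiaChannels pipeline report",
             paste0("config ", substr(manifest$config_hash, 1, 8),
                    ", seed ", manifest$seed, ", version ",
                    manifest$package_version), "")
  for (nm in names(manifest$stages)) {
    st <- manifest$stages[[nm]]
    if (!identical(st$status, "ok")) {
      lines <- c(lines, paste0("[", nm, "] FAILED: ", st$error), "")
      next
    }
    o <- st$outputs
    body <- switch(nm,
      overlap = c(
        paste0("  genes in >=k-of-n union: ", o$at_least_k,
               " (", o$consistent_down, " consistently down)"),
        paste0("  permutation p = ", .round2(o$p_value))),
      cic_dependence = c(
        paste0("  ", o$n_genes, " genes classified; planted-category ",
               "agreement ", .round2(100 * o$truth_agreement), "%")),
      ephys = c(
        paste0("  |C1+C2| = ", .round2(o$c_total_pF), " pF; area method ",
               .round2(o$c_area_pF), " pF (truth ",
               .round2(o$truth_c_total), " pF)"),
        paste0("  firing-class agreement ",
               .round2(100 * o$firing_truth_agreement),
               "%; AHP sweep ", o$ahp_sweep)),
      quant = c(
        paste0("  intensity effect ", .round2(o$intensity_effect_pct),
               "% (planted ", .round2(o$truth_effect_pct), "%)"),
        paste0("  standard-curve efficiency ",
               .round2(100 * o$curve_efficiency), "%")),
      paste0("  (no renderer for stage ", nm, ")"))
    lines <- c(lines, paste0("[", nm, "]"), body, "")
  }
  if (!is.null(file)) writeLines(lines, file)
  cat(lines, sep = "\n")
  invisible(lines)
}
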