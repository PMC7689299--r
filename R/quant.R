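#' A Ct measurement (technical replicates for one gene in one sample)
#'
#' @param gene gene symbol.
#' @param sampleId sample label.
#' @param group group label (genotype/region).
#' @param cts numeric vector of replicate cycle thresholds (typically a
#'   triplicate), each in (0, 45).
#' @return list of class \code{"ctMeasurement"}.
#' @export
ctMeasurement <- function(gene, sampleId, group, cts) {
  cts <- as.numeric(cts)
  if (length(cts) < 1L) stop("need at least one replicate Ct")
  if (any(!is.finite(cts)) || any(cts <= 0 | cts >= 45))
    stop("Ct values must lie in (0, 45)")
  structure(list(gene = gene, sampleId = sampleId, group = group, cts = cts),
            class = "ctMeasurement")
}

#' Comparative-Ct (delta-delta-Ct) relative expression
#'
#' Replicate Cts are averaged first; then
#' dCt = mean Ct(target) - mean Ct(reference),
#' ddCt = dCt - calibrator dCt, and fold = 2^(-ddCt). The amplification
#' base is fixed at 2 for the comparative-Ct path (the standard-curve path
#' carries a measured efficiency instead).
#'
#' @param target \code{\link{ctMeasurement}} for the gene of interest.
#' @param reference \code{\link{ctMeasurement}} for the reference gene
#'   (e.g. Actb) from the same sample.
#' @param calibratorDct the calibrator group's dCt, cycles.
#' @return list with \code{gene}, \code{sampleId}, \code{dct}, \code{ddct},
#'   \code{fold}, \code{referenceGene}.
#' @export
ddctFold <- function(target, reference, calibratorDct) {
  stopifnot(inherits(target, "ctMeasurement"),
            inherits(reference, "ctMeasurement"))
  if (!identical(target$sampleId, reference$sampleId))
    stop("target and reference Cts must come from the same sample (",
         target$sampleId, " vs ", reference$sampleId, ")")
  dct <- mean(target$cts) - mean(reference$cts)
  ddct <- dct - calibratorDct
  list(gene = target$gene, sampleId = target$sampleId, dct = dct,
       ddct = ddct, fold = 2^(-ddct), referenceGene = reference$gene)
}

#' Batch comparative-Ct quantification from a long Ct table
#'
#' For every gene and sample, averages replicate Cts, subtracts the
#' reference gene's mean Ct in the same sample, and normalizes against the
#' mean dCt of the calibrator group.
#'
#' @param ctTable data.frame with columns \code{gene}, \code{sample_id},
#'   \code{group}, \code{ct} (one row per replicate), as from
#'   \code{\link{readCtTable}}.
#' @param referenceGene reference gene symbol (default "Actb").
#' @param calibratorGroup group whose mean dCt defines the calibrator.
#' @return data.frame with one row per gene x sample: \code{gene},
#'   \code{sample_id}, \code{group}, \code{dct}, \code{ddct}, \code{fold}.
#' @export
ddctTable <- function(ctTable, referenceGene = "Actb", calibratorGroup) {
  stopifnot(all(c("gene", "sample_id", "group", "ct") %in% names(ctTable)))
  if (!referenceGene %in% ctTable$gene)
    stop("reference gene '", referenceGene, "' not in the Ct table")
  if (!calibratorGroup %in% ctTable$group)
    stop("calibrator group '", calibratorGroup, "' not in the Ct table")
  agg <- stats::aggregate(ct ~ gene + sample_id + group, data = ctTable,
                          FUN = mean)
  ref <- agg[agg$gene == referenceGene, ]
  tgt <- agg[agg$gene != referenceGene, ]
  ix <- match(tgt$sample_id, ref$sample_id)
  if (any(is.na(ix)))
    stop("sample(s) without a reference-gene measurement: ",
         paste(unique(tgt$sample_id[is.na(ix)]), collapse = ", "))
  tgt$dct <- tgt$ct - ref$ct[ix]
  out <- do.call(rbind, lapply(split(tgt, tgt$gene), function(g) {
    cal <- mean(g$dct[g$group == calibratorGroup])
    g$ddct <- g$dct - cal
    g$fold <- 2^(-g$ddct)
    g
  }))
  rownames(out) <- NULL
  out[, c("gene", "sample_id", "group", "dct", "ddct", "fold")]
}

#' Fit a qPCR standard curve
#'
#' Ordinary least-squares line of Ct against log10 quantity over an input
#' dilution series (e.g. 0.01-2 percent input). Reports the slope
#' (cycles per log10), intercept, R^2 and the amplification efficiency
#' 10^(-1/slope) - 1 (1 = 100 percent; a perfect curve has slope
#' -1/log10(2) = -3.3219).
#'
#' @param quantities input quantities (fractions or percents; units carry
#'   through to \code{\link{percentInput}}).
#' @param cts cycle thresholds at each quantity.
#' @return a \linkS4class{StandardCurve}.
#' @export
fitStandardCurve <- function(quantities, cts) {
  quantities <- as.numeric(quantities); cts <- as.numeric(cts)
  if (length(quantities) != length(cts)) stop("length mismatch")
  if (length(cts) < 3L) stop("need at least three dilution points")
  if (any(quantities <= 0)) stop("quantities must be positive")
  lq <- log10(quantities)
  if (diff(range(lq)) < 1) stop("dilution series must span at least 1 log10")
  fit <- stats::lm(cts ~ lq)
  slope <- unname(stats::coef(fit)[2L])
  if (slope >= 0)
    stop("non-monotone standard curve (slope >= 0): Ct must fall as ",
         "input quantity rises")
  methods::new("StandardCurve", logQuantities = lq, cts = cts,
               slope = slope, intercept = unname(stats::coef(fit)[1L]),
               rSquared = suppressWarnings(summary(fit)$r.squared),
               efficiency = 10^(-1 / slope) - 1)
}

#' ChIP-qPCR percent input
#'
#' Interpolates a ChIP sample's Ct on the input-dilution standard curve:
#' quantity = 10^((ct - intercept)/slope), in the curve's quantity units
#' (percent input when the curve was fit on percents). Cts more than one
#' cycle outside the standard range trigger an extrapolation warning.
#'
#' @param chipCt ChIP sample Ct (vectorized).
#' @param curve a \linkS4class{StandardCurve}.
#' @return numeric, percent input.
#' @export
percentInput <- function(chipCt, curve) {
  stopifnot(methods::is(curve, "StandardCurve"))
  lo <- min(curve@cts); hi <- max(curve@cts)
  if (any(chipCt < lo - 1 | chipCt > hi + 1))
    warning("Ct more than 1 cycle outside the standard-curve range ",
            sprintf("[%.2f, %.2f]; extrapolating", lo, hi))
  10^((chipCt - curve@intercept) / curve@slope)
}

#' Somatic intensity score from a line profile
#'
#' The somatic signal for one cell is the area under the intensity profile
#' drawn across the immunopositive area, divided by the length of the line:
#' trapezoidal AUC / (max position - min position).
#'
#' @param positions positions along the line, micrometers, increasing.
#' @param intensities intensity at each position, arbitrary units.
#' @return list with \code{auc}, \code{lineLength}, \code{score}.
#' @export
profileScore <- function(positions, intensities) {
  positions <- as.numeric(positions); intensities <- as.numeric(intensities)
  if (length(positions) < 2L) stop("need at least two samples along the line")
  if (any(diff(positions) <= 0)) stop("positions must be increasing")
  len <- max(positions) - min(positions)
  if (len <= 0) stop("zero-length line")
  auc <- pracma::trapz(positions, intensities)
  list(auc = auc, lineLength = len, score = auc / len)
}

#' Normalize per-cell intensity scores to a reference group
#'
#' Scores are first averaged within animal (the mean over that animal's
#' cells), then every animal mean is divided by the grand mean of the
#' reference group's animal means, so the reference group's normalized mean
#' is 1 by construction. Animals with zero cells are excluded with a
#' warning. The output is scale-invariant: multiplying all raw intensities
#' by a positive constant leaves it unchanged.
#'
#' @param scores data.frame with columns \code{animal}, \code{group},
#'   \code{score} (one row per cell).
#' @param referenceGroup the normalizing group label (e.g. wild-type
#'   anterior cerebellum).
#' @return data.frame with one row per animal: \code{animal}, \code{group},
#'   \code{nCells}, \code{meanScore}, \code{normalized}; attribute
#'   \code{"referenceMean"} records the denominator.
#' @export
normalizeScores <- function(scores, referenceGroup) {
  stopifnot(all(c("animal", "group", "score") %in% names(scores)))
  ok <- is.finite(scores$score)
  if (any(!ok)) {
    warning(sum(!ok), " cell(s) with non-finite scores excluded")
    scores <- scores[ok, ]
  }
  if (!referenceGroup %in% scores$group)
    stop("reference group '", referenceGroup, "' not present")
  perAnimal <- stats::aggregate(score ~ animal + group, data = scores,
                                FUN = mean)
  nCells <- stats::aggregate(score ~ animal + group, data = scores,
                             FUN = length)
  refMean <- mean(perAnimal$score[perAnimal$group == referenceGroup])
  out <- data.frame(animal = perAnimal$animal, group = perAnimal$group,
                    nCells = nCells$score,
                    meanScore = perAnimal$score,
                    normalized = perAnimal$score / refMean,
                    stringsAsFactors = FALSE)
  attr(out, "referenceMean") <- refMean
  out
}

#' Percent difference between two group means
#'
#' 100 (a - b) / b; the convention used to report, e.g., how much higher a
#' mutant group's normalized signal is than its control's.
#'
#' @param meanA numerator group mean.
#' @param meanB denominator (control) group mean; must be positive.
#' @return percent.
#' @export
percentDifference <- function(meanA, meanB) {
  if (meanB <= 0) stop("denominator mean must be positive")
  100 * (meanA - meanB) / meanB
}
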