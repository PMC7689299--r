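#' Assemble a three-contrast triple for dependence classification
#'
#' Bundles the three differential-expression contrasts used to classify
#' channel genes by their dependence on the ATXN1-Cic repressor complex:
#' (1) ATXN1[82Q] vs wild type, (2) the Cic-binding-deficient mutant
#' (ATXN1[82Q]V591A;S602D) vs wild type, and (3) mutant vs ATXN1[82Q]. The
#' three gene sets are reconciled to a common universe; in strict mode a
#' gene present in only some contrasts is an error, because silent absence
#' handling is the classic source of irreproducible category counts. The
#' escape hatch \code{fillAbsentNotDe} records absent genes as not DE with
#' an NA fold change.
#'
#' @param de82qVsWt,deMutVsWt,deMutVs82q data.frames as returned by
#'   \code{\link{readDETable}} (columns \code{gene}, \code{log2fc},
#'   \code{is_de}).
#' @param alpha the significance threshold the \code{is_de} flags encode
#'   (recorded, default 0.01).
#' @param fillAbsentNotDe treat genes absent from a contrast as not DE
#'   (default FALSE: strict mode, absence is an error).
#' @return a list of class \code{"contrastTriple"} with elements
#'   \code{genes}, \code{contrasts} (named list of aligned data.frames) and
#'   \code{alpha}.
#' @export
contrastTriple <- function(de82qVsWt, deMutVsWt, deMutVs82q, alpha = 0.01,
                           fillAbsentNotDe = FALSE) {
  contrasts <- list(de_82q_vs_wt = de82qVsWt, de_mut_vs_wt = deMutVsWt,
                    de_mut_vs_82q = deMutVs82q)
  for (nm in names(contrasts)) {
    tab <- contrasts[[nm]]
    stopifnot(is.data.frame(tab),
              all(c("gene", "log2fc", "is_de") %in% names(tab)))
    if (anyDuplicated(tab$gene))
      stop("duplicate gene(s) in contrast ", nm)
  }
  genes <- sort(unique(unlist(lapply(contrasts, `[[`, "gene"))))
  aligned <- lapply(names(contrasts), function(nm) {
    tab <- contrasts[[nm]]
    miss <- setdiff(genes, tab$gene)
    if (length(miss)) {
      if (!fillAbsentNotDe)
        stop("gene(s) absent from contrast ", nm, ": ",
             paste(utils::head(miss, 5L), collapse = ", "),
             if (length(miss) > 5L) ", ..." else "",
             " (use fillAbsentNotDe = TRUE to treat as not DE)")
      tab <- rbind(tab[, c("gene", "log2fc", "is_de")],
                   data.frame(gene = miss, log2fc = NA_real_, is_de = FALSE))
    }
    tab <- tab[match(genes, tab$gene), c("gene", "log2fc", "is_de")]
    rownames(tab) <- NULL
    tab
  })
  names(aligned) <- names(contrasts)
  structure(list(genes = genes, contrasts = aligned, alpha = alpha,
                 fillAbsentNotDe = fillAbsentNotDe),
            class = "contrastTriple")
}

#' Classify channel genes by ATXN1-Cic complex dependence
#'
#' Applies the two-criterion rule to each gene:
#' \itemize{
#'   \item \strong{dependent} -- DE in mutant-vs-82Q AND not DE in
#'     mutant-vs-WT (dysregulation abolished by disrupting the ATXN1-Cic
#'     association);
#'   \item \strong{partially_dependent} -- DE in mutant-vs-82Q AND DE in
#'     mutant-vs-WT (partial rescue);
#'   \item \strong{independent} -- not DE in mutant-vs-82Q, regardless of
#'     the other contrasts.
#' }
#' The three categories partition the gene set. The direction label (down /
#' up / none) comes from the 82Q-vs-WT contrast only. Genes DE in
#' mutant-vs-WT but in neither other contrast fall into "independent" by
#' the complement rule; this is recorded in the result's
#' \code{"note"} attribute rather than assumed biologically meaningful.
#'
#' @param triple a \code{\link{contrastTriple}}.
#' @param genes genes to classify (default: all genes in the triple).
#' @return data.frame with columns \code{gene}, \code{category},
#'   \code{direction_in_82q}.
#' @export
classifyDependence <- function(triple, genes = triple$genes) {
  stopifnot(inherits(triple, "contrastTriple"))
  unknown <- setdiff(genes, triple$genes)
  if (length(unknown))
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  ix <- match(genes, triple$genes)
  de82 <- triple$contrasts$de_82q_vs_wt[ix, ]
  deMW <- triple$contrasts$de_mut_vs_wt[ix, ]
  deM8 <- triple$contrasts$de_mut_vs_82q[ix, ]

  category <- ifelse(!deM8$is_de, "independent",
                     ifelse(deMW$is_de, "partially_dependent", "dependent"))
  direction <- ifelse(!de82$is_de, "none",
                      ifelse(de82$log2fc < 0, "down", "up"))
  out <- data.frame(gene = genes, category = category,
                    direction_in_82q = direction, stringsAsFactors = FALSE)
  attr(out, "alpha") <- triple$alpha
  attr(out, "note") <- paste(
    "genes DE only in the mutant-vs-WT contrast are labeled 'independent'",
    "by the complement rule")
  out
}

#' Log2 fold-change panel across the three contrasts
#'
#' One row per requested gene with the log2 fold change in each comparison,
#' in the standard column order (82Q vs WT; mutant vs WT; mutant vs 82Q).
#' Full precision is stored; rounding to two decimals happens only at
#' presentation (see \code{\link{pipelineReport}}).
#'
#' @param triple a \code{\link{contrastTriple}}.
#' @param genes genes to report.
#' @return data.frame with columns \code{gene}, \code{lfc_82q_vs_wt},
#'   \code{lfc_mut_vs_wt}, \code{lfc_mut_vs_82q}.
#' @export
log2fcPanel <- function(triple, genes) {
  stopifnot(inherits(triple, "contrastTriple"))
  unknown <- setdiff(genes, triple$genes)
  if (length(unknown))
    stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  ix <- match(genes, triple$genes)
  data.frame(gene = genes,
             lfc_82q_vs_wt = triple$contrasts$de_82q_vs_wt$log2fc[ix],
             lfc_mut_vs_wt = triple$contrasts$de_mut_vs_wt$log2fc[ix],
             lfc_mut_vs_82q = triple$contrasts$de_mut_vs_82q$log2fc[ix],
             stringsAsFactors = FALSE)
}
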