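#' Filter a DE table down to channel genes
#'
#' Retains the genes flagged differentially expressed that belong to the
#' channel universe, and assigns each a direction from the sign of its log2
#' fold change.
#'
#' @param records data.frame as returned by \code{\link{readDETable}}.
#' @param universe a \linkS4class{ChannelUniverse}.
#' @param modelId label for the model this table comes from.
#' @return a \linkS4class{ModelDESet}.
#' @export
filterChannels <- function(records, universe, modelId) {
  stopifnot(is.data.frame(records), methods::is(universe, "ChannelUniverse"))
  keep <- records[records$is_de %in% TRUE &
                    records$gene %in% universe@genes, , drop = FALSE]
  keep <- keep[!duplicated(keep$gene), , drop = FALSE]
  if (nrow(keep)) {
    bad <- !is.finite(keep$log2fc) | keep$log2fc == 0
    if (any(bad))
      stop("cannot assign a direction (log2fc zero or missing) for ",
           "retained channel gene(s): ",
           paste(keep$gene[bad], collapse = ", "))
  }
  dirs <- ifelse(keep$log2fc < 0, "down", "up")
  names(dirs) <- keep$gene
  methods::new("ModelDESet", modelId = modelId,
               deChannels = as.character(keep$gene),
               directions = if (nrow(keep)) dirs else
                 stats::setNames(character(0), character(0)))
}

.subsetNames <- function(models) {
  n <- length(models)
  masks <- .subsetMasks(n)
  vapply(masks, function(m)
    paste(models[bitwAnd(bitwShiftL(1L, seq_len(n) - 1L), m) != 0L],
          collapse = "+"), character(1))
}

# all nonempty subset bitmasks ordered by degree, then by model order
.subsetMasks <- function(n) {
  masks <- seq_len(2L^n - 1L)
  deg <- vapply(masks, .popcount, integer(1))
  masks[order(deg, masks)]
}

.popcount <- function(m) {
  k <- 0L
  while (m > 0L) { k <- k + bitwAnd(m, 1L); m <- bitwShiftR(m, 1L) }
  k
}

#' Cross-model overlap summary with UpSet semantics
#'
#' Counts, for every nonempty subset of models, the genes differentially
#' expressed in exactly that subset (the exclusive intersections an UpSet
#' plot displays), and forms the at-least-k unions. The headline statistic
#' of the cross-model comparison is the size of the at-least-\code{kStar}
#' union, with its consistently downregulated subset (genes whose direction
#' is down in every model where they are DE).
#'
#' @param sets list of \linkS4class{ModelDESet} objects (>= 2, distinct
#'   model ids).
#' @param kStar membership threshold for the headline union (default 3, the
#'   "at least three of four models" rule).
#' @return an \linkS4class{OverlapSummary}.
#' @export
computeOverlaps <- function(sets, kStar = 3L) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  models <- vapply(sets, modelId, character(1))
  if (anyDuplicated(models))
    stop("duplicate model id(s): ",
         paste(unique(models[duplicated(models)]), collapse = ", "))
  n <- length(models)
  kStar <- as.integer(kStar)
  if (kStar < 1L || kStar > n) stop("kStar must lie in [1, number of models]")

  geneSets <- lapply(sets, deChannels)
  allGenes <- sort(unique(unlist(geneSets)))
  member <- vapply(geneSets, function(g) allGenes %in% g,
                   logical(length(allGenes)))
  if (length(allGenes) == 1L) member <- matrix(member, nrow = 1L)
  if (length(allGenes) == 0L)
    member <- matrix(logical(0), nrow = 0L, ncol = n)

  geneMask <- as.integer(member %*% bitwShiftL(1L, seq_len(n) - 1L))
  masks <- .subsetMasks(n)
  excl <- vapply(masks, function(m) sum(geneMask == m), integer(1))
  names(excl) <- .subsetNames(models)

  degree <- rowSums(member)
  atLeastK <- lapply(seq_len(n), function(k) allGenes[degree >= k])
  names(atLeastK) <- as.character(seq_len(n))

  headline <- atLeastK[[as.character(kStar)]]
  consDown <- headline[vapply(headline, function(g) {
    inModels <- which(vapply(sets, function(s) g %in% deChannels(s),
                             logical(1)))
    all(vapply(sets[inModels], function(s) directions(s)[[g]] == "down",
               logical(1)))
  }, logical(1))]

  methods::new("OverlapSummary", models = models, exclusiveCounts = excl,
               atLeastK = atLeastK, kStar = kStar,
               consistentDown = as.character(consDown))
}

# evaluate an expression with a private RNG stream, restoring global state
.withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Permutation test for the cross-model overlap statistic
#'
#' Tests the null hypothesis that the observed number of channel genes in
#' the at-least-\code{kStar} union could arise by chance given each model's
#' number of DE channel genes. Each simulation independently samples, for
#' every model, its number of channels uniformly without replacement from
#' the channel universe, then counts the genes present in at least
#' \code{kStar} samples. The p-value uses the add-one estimator
#' (nGe + 1)/(nSims + 1), which can never return zero; the raw proportion
#' nGe/nSims is also reported. Ties at the observed value count toward the
#' tail (>=, not >).
#'
#' @param drawSizes integer vector, per-model numbers of DE channel genes.
#' @param universeSize size of the channel universe.
#' @param observed observed at-least-k union size.
#' @param kStar membership threshold.
#' @param nSims number of simulations (default 1000, matching the original
#'   procedure).
#' @param seed RNG seed (recorded in the result; global RNG state is left
#'   untouched).
#' @return a \linkS4class{PermutationResult}.
#' @export
permutationOverlapTest <- function(drawSizes, universeSize, observed,
                                   kStar = 3L, nSims = 1000L, seed = 1L) {
  drawSizes <- as.integer(drawSizes)
  universeSize <- as.integer(universeSize)
  nSims <- as.integer(nSims)
  if (any(drawSizes > universeSize))
    stop("draw size exceeds universe size")
  if (any(drawSizes < 0L) || nSims < 1L)
    stop("draw sizes must be nonnegative and nSims >= 1")
  kStar <- as.integer(kStar)
  stats <- .withSeed(seed, {
    vapply(seq_len(nSims), function(i) {
      samp <- unlist(lapply(drawSizes, function(d)
        sample.int(universeSize, d)))
      sum(tabulate(samp, nbins = universeSize) >= kStar)
    }, integer(1))
  })
  nGe <- sum(stats >= observed)
  methods::new("PermutationResult", observed = as.integer(observed),
               nSims = nSims, nGe = as.integer(nGe),
               pValue = (nGe + 1) / (nSims + 1), pRaw = nGe / nSims,
               seed = as.integer(seed), universeSize = universeSize,
               drawSizes = drawSizes, kStar = kStar)
}

# vectorized popcount over 16-bit halves (lookup table built once)
.popcountEnv <- new.env(parent = emptyenv())
.popcountVec <- function(x) {
  if (is.null(.popcountEnv$tab)) {
    tab <- integer(65536L)
    for (b in 0:15) tab <- tab + bitwAnd(bitwShiftR(0:65535L, b), 1L)
    .popcountEnv$tab <- tab
  }
  tab <- .popcountEnv$tab
  tab[bitwAnd(x, 65535L) + 1L] + tab[bitwShiftR(x, 16L) + 1L]
}

#' Exact null distribution of the overlap statistic
#'
#' Brute-force enumeration oracle for \code{\link{permutationOverlapTest}}:
#' enumerates every labeled combination of per-model subsets of the universe
#' and tallies the at-least-k statistic. Only feasible for small
#' configurations; the enumeration budget guards against blow-up.
#'
#' @param drawSizes per-model draw sizes.
#' @param universeSize universe size (<= 30).
#' @param kStar membership threshold.
#' @param budget maximum number of labeled combinations (default 2e6).
#' @return named numeric vector mapping statistic value to probability
#'   (sums to 1).
#' @export
exactOverlapDistribution <- function(drawSizes, universeSize, kStar,
                                     budget = 2e6) {
  drawSizes <- as.integer(drawSizes)
  universeSize <- as.integer(universeSize)
  kStar <- as.integer(kStar)
  if (universeSize > 30L) stop("universe too large for bitmask enumeration")
  if (any(drawSizes > universeSize)) stop("draw size exceeds universe size")
  total <- prod(choose(universeSize, drawSizes))
  if (total > budget)
    stop("enumeration budget exceeded (", format(total, big.mark = ","),
         " combinations); use permutationOverlapTest instead")

  maskList <- lapply(drawSizes, function(d) {
    if (d == 0L) return(0L)
    cmb <- utils::combn(universeSize, d)
    as.integer(apply(cmb, 2L, function(ix) sum(bitwShiftL(1L, ix - 1L))))
  })

  n <- length(drawSizes)
  freq <- integer(universeSize + 1L)  # statistic in 0..universeSize
  lastMasks <- maskList[[n]]
  lastPop <- .popcountVec(lastMasks)

  recurse <- function(depth, counts) {
    if (depth == n) {
      if (kStar == 1L) {
        # every gene in the last draw plus genes already present
        base <- sum(counts >= 1L)
        newMask <- sum(bitwShiftL(1L, which(counts == 0L) - 1L))
        stat <- base + .popcountVec(bitwAnd(lastMasks, as.integer(newMask)))
      } else {
        base <- sum(counts >= kStar)
        tip <- which(counts == kStar - 1L)
        tipMask <- if (length(tip)) sum(bitwShiftL(1L, tip - 1L)) else 0L
        stat <- base + .popcountVec(bitwAnd(lastMasks, as.integer(tipMask)))
      }
      tab <- tabulate(stat + 1L, nbins = universeSize + 1L)
      freq <<- freq + tab
      return(invisible())
    }
    for (m in maskList[[depth]]) {
      bits <- bitwAnd(bitwShiftR(m, seq_len(universeSize) - 1L), 1L)
      recurse(depth + 1L, counts + bits)
    }
  }
  if (n == 1L) {
    stat <- if (kStar <= 1L) lastPop else rep(0L, length(lastMasks))
    freq <- tabulate(stat + 1L, nbins = universeSize + 1L)
  } else {
    recurse(1L, integer(universeSize))
  }
  probs <- freq / total
  names(probs) <- as.character(0:universeSize)
  probs <- probs[probs > 0 | seq_along(probs) <= max(which(probs > 0), 1L)]
  stopifnot(abs(sum(probs) - 1) < 1e-12)
  probs
}

#' Exact tail probability P(statistic >= observed)
#'
#' @param dist distribution from \code{\link{exactOverlapDistribution}}.
#' @param observed observed statistic.
#' @return probability.
#' @export
exactTailProbability <- function(dist, observed) {
  sum(dist[as.integer(names(dist)) >= observed])
}

#' Export the UpSet exclusive-intersection table (and figure)
#'
#' Writes the exclusive-intersection count matrix as a tab-separated table
#' (the machine-testable artifact): one row per nonempty model subset
#' ordered by degree then model order, with one indicator column per model,
#' the degree, and the exclusive count. When the ComplexHeatmap package is
#' available a rendered UpSet figure is written alongside.
#'
#' @param summary an \linkS4class{OverlapSummary}.
#' @param path output TSV path.
#' @param plotPath optional PDF path for the rendered UpSet figure (NULL to
#'   skip).
#' @return invisibly, the table as a data.frame.
#' @export
exportUpset <- function(summary, path, plotPath = NULL) {
  stopifnot(methods::is(summary, "OverlapSummary"))
  if (sum(summary@exclusiveCounts) == 0L)
    stop("empty overlap summary: no genes in any model set")
  models <- summary@models
  n <- length(models)
  masks <- .subsetMasks(n)
  ind <- t(vapply(masks, function(m)
    as.integer(bitwAnd(bitwShiftL(1L, seq_len(n) - 1L), m) != 0L),
    integer(n)))
  colnames(ind) <- models
  tab <- data.frame(subset = names(summary@exclusiveCounts), ind,
                    degree = rowSums(ind),
                    count = as.integer(summary@exclusiveCounts),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(plotPath) &&
      requireNamespace("ComplexHeatmap", quietly = TRUE)) {
    cm <- ind[tab$count > 0, , drop = FALSE]
    m <- cm[rep(seq_len(nrow(cm)), tab$count[tab$count > 0]), , drop = FALSE]
    grDevices::pdf(plotPath, width = 7, height = 4)
    ComplexHeatmap::draw(ComplexHeatmap::UpSet(t(m)))
    grDevices::dev.off()
  }
  invisible(tab)
}
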