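# small in-code fixtures shared across test files

makeDeTable <- function(genes, lfc, padj = rep(1e-4, length(genes)),
                        isDe = padj < 0.01) {
  data.frame(gene = genes, log2fc = lfc, padj = padj, is_de = isDe,
             stringsAsFactors = FALSE)
}

makeSet <- function(id, genes, dirs = rep("down", length(genes))) {
  new("ModelDESet", modelId = id, deChannels = genes,
      directions = stats::setNames(dirs, genes))
}

smallUniverse <- function(genes = c("Kcnma1", "Cacna1g", "Trpc3", "Kcnc3")) {
  new("ChannelUniverse", genes = genes, label = "test")
}

writeTempDeFile <- function(df, sep = "\t", ext = ".tsv") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# exact two-exponential fit fixture from known circuit parameters
exactFitObject <- function(c1, c2, r1, r2, deltaV, iSS = -100) {
  par <- twoCompartmentInverse(c1, c2, r1, r2, deltaV)
  new("TwoExponentialFit", a1 = par$a1, tau1 = par$tau1, a2 = par$a2,
      tau2 = par$tau2, iSS = iSS, deltaV = deltaV, rss = 0,
      converged = TRUE, degenerate = FALSE, diagnostics = list())
}
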