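#' Normalize gene symbols to the mouse convention
#'
#' Mouse gene symbols are title-cased (first letter upper, remainder lower).
#' The four source DE tables mix microarray- and RNA-seq-era annotation
#' styles, so every symbol is normalized before any set operation. The
#' transformation is idempotent.
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized symbols.
#' @examples
#' normalizeGeneSymbols(c("KCNMA1", "cacna1g", "Trpc3"))
#' @export
normalizeGeneSymbols <- function(x) {
  x <- trimws(as.character(x))
  out <- tolower(x)
  substr(out, 1L, 1L) <- toupper(substr(out, 1L, 1L))
  out[!nzchar(x)] <- ""
  out
}

.readDelim <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "#")
}

#' Read a differential-expression gene table
#'
#' Reads a delimited DE table as produced by an upstream DESeq2 or
#' microarray analysis. A column-mapping list adapts to each source table's
#' headers rather than hard-coding any repository layout. When the table has
#' no explicit DE flag column, the flag is derived as \code{padj < alpha};
#' tables without an adjusted-p column (older microarray exports) must carry
#' an explicit flag. Rows whose numeric fields fail to parse are kept with
#' NA and reported via a warning, never silently dropped.
#'
#' @param path file path (TSV by default, CSV by extension).
#' @param columns named list mapping the fields \code{gene}, \code{log2fc},
#'   \code{padj}, \code{is_de} to the file's column names. \code{padj} and
#'   \code{is_de} entries may be NA when absent from the file.
#' @param alpha significance threshold used when deriving \code{is_de} from
#'   \code{padj} (default 0.01, the threshold used for the RNA-seq
#'   contrasts).
#' @param normalize normalize gene symbols to the mouse convention
#'   (default TRUE).
#' @param sep field separator; inferred from the extension when NULL.
#' @return data.frame with columns \code{gene}, \code{log2fc}, \code{padj},
#'   \code{is_de}; attribute \code{"alpha"} records the threshold.
#' @export
readDETable <- function(path,
                        columns = list(gene = "gene", log2fc = "log2fc",
                                       padj = "padj", is_de = "is_de"),
                        alpha = 0.01, normalize = TRUE, sep = NULL) {
  tab <- .readDelim(path, sep)
  if (nrow(tab) == 0L) stop("empty DE table: ", path)
  for (f in c("gene", "log2fc")) {
    cn <- columns[[f]]
    if (is.null(cn) || is.na(cn) || !cn %in% names(tab))
      stop("DE table ", path, " is missing required column '", f,
           "' (mapped to '", if (is.null(cn)) f else cn, "')")
  }
  gene <- as.character(tab[[columns$gene]])
  if (normalize) gene <- normalizeGeneSymbols(gene)
  if (any(!nzchar(gene))) stop("empty gene symbol in ", path)

  asNum <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & !is.na(v) & nzchar(trimws(as.character(v))) &
                   !toupper(trimws(as.character(v))) %in% c("NA", "NAN"))
    if (length(bad))
      warning(length(bad), " row(s) with unparseable ", what, " in ", path,
              " (rows ", paste(utils::head(bad, 5L), collapse = ", "),
              if (length(bad) > 5L) ", ..." else "", "); kept as NA")
    out
  }
  log2fc <- asNum(tab[[columns$log2fc]], "log2fc")

  padjCol <- columns$padj
  hasPadj <- !is.null(padjCol) && !is.na(padjCol) && padjCol %in% names(tab)
  padj <- if (hasPadj) asNum(tab[[padjCol]], "padj") else rep(NA_real_, nrow(tab))
  if (any(padj < 0 | padj > 1, na.rm = TRUE))
    stop("padj values outside [0, 1] in ", path)

  deCol <- columns$is_de
  hasDe <- !is.null(deCol) && !is.na(deCol) && deCol %in% names(tab)
  if (hasDe) {
    isDe <- as.logical(tab[[deCol]])
  } else if (hasPadj) {
    isDe <- !is.na(padj) & padj < alpha
  } else {
    stop("DE table ", path, " has neither an 'is_de' flag column nor a ",
         "'padj' column to derive it from")
  }

  out <- data.frame(gene = gene, log2fc = log2fc, padj = padj, is_de = isDe,
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  out
}

#' Write a DE table
#'
#' @param records data.frame as returned by \code{\link{readDETable}}.
#' @param path output path (TSV).
#' @return invisibly, the path.
#' @export
writeDETable <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a channel-universe gene list
#'
#' One symbol per line; lines starting with \code{#} are comments.
#' Duplicates (after normalization) are collapsed with a warning and the
#' final size is reported.
#'
#' @param path file path.
#' @param label provenance label stored on the object (defaults to the file
#'   name).
#' @param normalize normalize symbols to the mouse convention.
#' @return a \linkS4class{ChannelUniverse}.
#' @export
readUniverse <- function(path, label = basename(path), normalize = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (normalize) lines <- normalizeGeneSymbols(lines)
  if (length(lines) == 0L) stop("empty channel universe: ", path)
  if (anyDuplicated(lines)) {
    dups <- unique(lines[duplicated(lines)])
    warning("collapsed ", length(lines) - length(unique(lines)),
            " duplicate universe entrie(s): ",
            paste(utils::head(dups, 5L), collapse = ", "))
    lines <- unique(lines)
  }
  message("channel universe '", label, "': ", length(lines), " genes")
  methods::new("ChannelUniverse", genes = lines, label = label)
}

#' Bundled channel-universe fixture
#'
#' Path to the bundled 270-symbol mouse pore-forming (alpha subunit) ion
#' channel gene list. This file is a curated synthetic stand-in snapshot
#' assembled from the standard channel gene families (voltage-gated K, Na
#' and Ca channels, TRP, ligand-gated, and other pore-forming subunits); it
#' matches the size and composition style of the IUPHAR mouse list but is
#' not a download of it.
#'
#' @return file path.
#' @export
channelUniverseFixture <- function() {
  system.file("extdata", "iuphar_mouse_channels_synthetic.txt",
              package = "ataxiaChannels", mustWork = TRUE)
}

.fmt <- function(x) sprintf("%.17g", x)

#' Write a recording trace with its metadata sidecar
#'
#' Two-column tab-separated text (time in seconds, signal in pA or mV) plus
#' a YAML sidecar carrying the recording metadata. Values are written with
#' 17 significant digits so the write/read round trip is exact at double
#' precision.
#'
#' @param trace a \linkS4class{TraceRecording}.
#' @param path trace file path.
#' @param sidecarPath sidecar path (default: \code{path} with a
#'   \code{.meta.yaml} suffix).
#' @return invisibly, c(path, sidecarPath).
#' @export
writeTrace <- function(trace, path, sidecarPath = paste0(path, ".meta.yaml")) {
  stopifnot(methods::is(trace, "TraceRecording"))
  colname <- if (trace@mode == "voltage_clamp") "current_pA" else "voltage_mV"
  df <- data.frame(time_s = .fmt(trace@time), sig = .fmt(trace@signal))
  names(df)[2] <- colname
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(list(mode = trace@mode, sampling_rate_hz = trace@samplingRate),
            trace@metadata)
  yaml::write_yaml(meta, sidecarPath, precision = 17)
  invisible(c(path, sidecarPath))
}

#' Read a recording trace and its metadata sidecar
#'
#' @param path two-column delimited trace file (time + signal, header row).
#' @param sidecarPath YAML sidecar with \code{mode},
#'   \code{sampling_rate_hz} and recording metadata.
#' @return a \linkS4class{TraceRecording}.
#' @export
readTrace <- function(path, sidecarPath = paste0(path, ".meta.yaml")) {
  tab <- .readDelim(path)
  if (ncol(tab) < 2L) stop("trace file must have two columns: ", path)
  if (!file.exists(sidecarPath)) stop("sidecar not found: ", sidecarPath)
  meta <- yaml::read_yaml(sidecarPath)
  for (k in c("mode", "sampling_rate_hz"))
    if (is.null(meta[[k]])) stop("sidecar ", sidecarPath, " missing '", k, "'")
  mode <- meta$mode
  fs <- as.numeric(meta$sampling_rate_hz)
  meta$mode <- NULL; meta$sampling_rate_hz <- NULL
  if (mode == "voltage_clamp")
    for (k in c("step_mV", "holding_mV"))
      if (is.null(meta[[k]]))
        stop("voltage-clamp trace sidecar missing required key '", k, "'")
  time <- as.numeric(tab[[1L]])
  if (length(time) >= 2L) {
    dt <- diff(time)
    step <- stats::median(dt)
    if (any(dt <= 0) || max(abs(dt - step)) > 1e-6 * step)
      stop("non-uniform time step in trace ", path)
  }
  methods::new("TraceRecording", time = time, signal = as.numeric(tab[[2L]]),
               mode = mode, samplingRate = fs, metadata = meta)
}

#' Read a qPCR Ct table
#'
#' Long-format delimited table with columns \code{gene}, \code{sample_id},
#' \code{group} and \code{ct} (one row per technical replicate).
#'
#' @param path file path.
#' @return data.frame with those columns.
#' @export
readCtTable <- function(path) {
  tab <- .readDelim(path)
  need <- c("gene", "sample_id", "group", "ct")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("Ct table ", path, " missing column(s): ", paste(miss, collapse = ", "))
  tab$ct <- as.numeric(tab$ct)
  if (any(!is.finite(tab$ct)) || any(tab$ct <= 0 | tab$ct >= 45))
    stop("Ct values must lie in (0, 45): ", path)
  tab[need]
}

#' Embed reproducibility metadata and write a result as JSON
#'
#' Every machine-readable analysis output carries the configuration hash,
#' the RNG seed and the package version.
#'
#' @param x list of results.
#' @param path output path.
#' @param seed RNG seed used (or NA for deterministic stages).
#' @param config configuration object hashed into the output.
#' @return invisibly, the path.
#' @export
writeResultJSON <- function(x, path, seed = NA_integer_, config = list()) {
  x$provenance <- list(
    config_hash = configHash(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("ataxiaChannels")))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Hash a configuration object
#'
#' MD5 of the canonical serialized form, used to stamp outputs and detect
#' configuration drift between runs.
#'
#' @param config any R object.
#' @return 32-character hex string.
#' @export
configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(config, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}
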