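#' Read an expression panel from matrix + metadata TSV files
#'
#' The matrix file is tab-separated with a header of sample ids and gene
#' ids in the first column; the metadata file has one row per sample with
#' columns `sample_id`, `compound`, `dose`, `time`, `replicate`, `system`.
#' Samples are matched by id; metadata row order is irrelevant. Malformed
#' inputs (duplicate genes, unmatched samples) are rejected, never repaired.
#'
#' @param matrixPath path to the gene x sample TSV.
#' @param metadataPath path to the sample metadata TSV.
#' @return an [ExpressionPanel-class].
#' @export
readExpressionPanel <- function(matrixPath, metadataPath) {
  tab <- utils::read.delim(matrixPath, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = NA)
  if (ncol(tab) < 2L)
    stop("expression matrix must have a gene id column and >=1 sample")
  genes <- as.character(tab[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene id in expression matrix: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  meta <- utils::read.delim(metadataPath, header = TRUE, sep = "\t",
                            check.names = FALSE,
                            colClasses = c(sample_id = "character"))
  ExpressionPanel(values, meta)
}

#' Write an expression panel to matrix + metadata TSV files
#'
#' @param panel an [ExpressionPanel-class].
#' @param matrixPath,metadataPath output paths.
#' @return invisibly, the two paths.
#' @export
writeExpressionPanel <- function(panel, matrixPath, metadataPath) {
  m <- assay(panel, "log2")
  df <- data.frame(gene_id = rownames(m), signif(m, 12),
                   check.names = FALSE)
  utils::write.table(df, matrixPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cd <- as.data.frame(colData(panel))
  meta <- data.frame(sample_id = rownames(cd), cd, check.names = FALSE)
  utils::write.table(meta, metadataPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrixPath, metadataPath))
}

#' Read a gene-to-abstract annotation file (gene2pubmed dialect)
#'
#' Tab-separated columns: taxon id, gene id, abstract (PubMed) id, with an
#' optional leading `#` header line. Duplicate (gene, abstract) pairs are
#' collapsed; rows of other taxa are dropped when `taxonFilter` is given.
#'
#' @param path input file.
#' @param taxonFilter optional taxon id; keep only matching rows.
#' @return named list mapping gene id to a character vector of abstract ids.
#' @export
readGeneAbstractMap <- function(path, taxonFilter = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(structure(list(), names = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed gene2pubmed row at line ", bad[1L])
  taxon <- vapply(parts, `[[`, "", 1L)
  gene <- vapply(parts, `[[`, "", 2L)
  abstract <- vapply(parts, `[[`, "", 3L)
  if (anyNA(suppressWarnings(as.integer(taxon))) ||
      anyNA(suppressWarnings(as.integer(abstract))))
    stop("non-integer taxon or abstract id in ", path)
  if (!is.null(taxonFilter)) {
    keep <- taxon == as.character(taxonFilter)
    gene <- gene[keep]; abstract <- abstract[keep]
  }
  if (!length(gene)) return(structure(list(), names = character(0)))
  lapply(split(abstract, gene), unique)
}

#' Read a homolog group table (HomoloGene dialect)
#'
#' Tab-separated columns: group id, taxon id, gene id; extra columns are
#' ignored. A malformed row is reported with its line number.
#'
#' @param path input file.
#' @return data.frame with columns `group_id`, `taxon_id`, `gene_id`.
#' @export
readHomologTable <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(data.frame(group_id = character(0), taxon_id = character(0),
                      gene_id = character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("malformed homolog row at line ", lineNo[bad[1L]], " of ", path)
  out <- data.frame(group_id = vapply(parts, `[[`, "", 1L),
                    taxon_id = vapply(parts, `[[`, "", 2L),
                    gene_id = vapply(parts, `[[`, "", 3L))
  dup <- duplicated(out)
  out[!dup, , drop = FALSE]
}

#' Read a topic abstract-id set (one id per line)
#'
#' @param path input file.
#' @return character vector of abstract ids.
#' @export
readTopicSet <- function(path) {
  x <- readLines(path)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Write / read an aggregated ranking as TSV
#'
#' The file has columns `gene_id`, `score`, `rank` (plus `pvalue`/`qvalue`
#' when present), sorted by rank; numeric values are written with 12+
#' significant digits so a write-read round trip preserves them.
#'
#' @param result an [AggregationResult-class].
#' @param path output (input) path.
#' @return `writeRanking` invisibly returns `path`; `readRanking` returns
#'   an [AggregationResult-class].
#' @export
writeRanking <- function(result, path) {
  ord <- order(result@rank, names(result@rank))
  df <- data.frame(gene_id = names(result@rank)[ord],
                   score = format(result@score[ord], digits = 15,
                                  scientific = TRUE, trim = TRUE),
                   rank = format(result@rank[ord], digits = 15, trim = TRUE))
  if (length(result@pvalue))
    df$pvalue <- format(result@pvalue[ord], digits = 15,
                        scientific = TRUE, trim = TRUE)
  if (length(result@qvalue))
    df$qvalue <- format(result@qvalue[ord], digits = 15,
                        scientific = TRUE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRanking
#' @param method method label to attach on read; defaults to the file name.
#' @export
readRanking <- function(path, method = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  need <- c("gene_id", "score", "rank")
  if (!all(need %in% colnames(df)))
    stop("ranking file must have columns gene_id, score, rank")
  if (is.null(method))
    method <- sub("\\.tsv$", "", basename(path))
  score <- stats::setNames(as.numeric(df$score), df$gene_id)
  rank <- stats::setNames(as.numeric(df$rank), df$gene_id)
  p <- if ("pvalue" %in% colnames(df))
    stats::setNames(as.numeric(df$pvalue), df$gene_id) else numeric(0)
  q <- if ("qvalue" %in% colnames(df))
    stats::setNames(as.numeric(df$qvalue), df$gene_id) else numeric(0)
  AggregationResult(method, score, rank, p, q)
}

#' Write / read a per-compound extended partial ranking as TSV
#'
#' Columns: `gene_id`, `rank`, `modulated` (0/1 flag).
#'
#' @param rl a [RankedList-class].
#' @param path output (input) path.
#' @export
writeRankedList <- function(rl, path) {
  ord <- order(rl@ranks, names(rl@ranks))
  df <- data.frame(gene_id = names(rl@ranks)[ord],
                   rank = format(rl@ranks[ord], digits = 15, trim = TRUE),
                   modulated = as.integer(names(rl@ranks)[ord] %in%
                                            rl@modulated))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRankedList
#' @export
readRankedList <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (!all(c("gene_id", "rank", "modulated") %in% colnames(df)))
    stop("ranked-list file must have columns gene_id, rank, modulated")
  RankedList(stats::setNames(as.numeric(df$rank), df$gene_id),
             df$gene_id[df$modulated == "1"])
}

#' Write / read a differential-expression result table as TSV
#'
#' @param de data.frame as returned by [deAnalysis()].
#' @param path output (input) path.
#' @export
writeDEResults <- function(de, path) {
  out <- de
  for (cn in c("global_q", "adjusted_p", "r2"))
    out[[cn]] <- format(out[[cn]], digits = 15, scientific = TRUE,
                        trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeDEResults
#' @export
readDEResults <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = c(gene_id = "character"))
  for (cn in c("passed_global", "has_significant_coef", "selected"))
    df[[cn]] <- as.logical(df[[cn]])
  df
}

#' Write a gene-to-abstract map in gene2pubmed dialect
#'
#' @param map named list mapping gene id to abstract ids.
#' @param path output path.
#' @param taxon taxon id stamped on every row.
#' @export
writeGeneAbstractMap <- function(map, path, taxon = 9606L) {
  genes <- rep(names(map), lengths(map))
  df <- data.frame(taxon, genes, unlist(map, use.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#tax_id\tGeneID\tPubMed_ID", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a topic abstract-id set (one id per line)
#'
#' @param topic character vector of abstract ids.
#' @param path output path.
#' @export
writeTopicSet <- function(topic, path) {
  writeLines(as.character(topic), path)
  invisible(path)
}

#' Write a homolog group table in HomoloGene dialect
#'
#' @param table data.frame with columns `group_id`, `taxon_id`, `gene_id`.
#' @param path output path.
#' @export
writeHomologTable <- function(table, path) {
  utils::write.table(table[c("group_id", "taxon_id", "gene_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
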