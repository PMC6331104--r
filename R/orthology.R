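#' Read a probeset-to-gene map (two-column TSV)
#'
#' Columns `probeset`, `gene`; a probeset mapping to several genes appears
#' on several rows.
#'
#' @param path input file.
#' @return data.frame with columns `probeset`, `gene`.
#' @export
readProbesetMap <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  if (!all(c("probeset", "gene") %in% colnames(df)))
    stop("probeset map must have columns 'probeset' and 'gene'")
  unique(df)
}

#' Collapse probeset rows to one representative row per gene
#'
#' Probesets mapping to more than one gene are removed as non-specific.
#' When several probesets map to one gene, the probeset with the largest
#' interquartile range of expression across all samples is kept (the most
#' variant, hence presumably most informative); IQR ties are broken by
#' lexicographically smallest probeset id. Retained rows are verbatim
#' copies of input rows, re-keyed by gene id.
#'
#' @param values probeset x sample numeric matrix (probeset ids as
#'   rownames), or an [ExpressionPanel-class] whose rows are probesets.
#' @param pmap probeset-to-gene map as returned by [readProbesetMap()].
#' @return object of the same kind as `values`, with gene ids as rownames.
#' @export
collapseProbesets <- function(values, pmap) {
  isPanel <- is(values, "ExpressionPanel")
  m <- if (isPanel) assay(values, "log2") else as.matrix(values)
  if (is.null(rownames(m)))
    stop("'values' must have probeset ids as rownames")
  unknown <- setdiff(rownames(m), pmap$probeset)
  if (length(unknown))
    stop("probeset(s) missing from the map: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  genesPer <- table(unique(pmap[c("probeset", "gene")])$probeset)
  specific <- names(genesPer)[genesPer == 1L]
  pmap <- pmap[pmap$probeset %in% specific &
                 pmap$probeset %in% rownames(m), , drop = FALSE]
  if (!nrow(pmap))
    stop("no specific probesets left after filtering")
  iqr <- apply(m[pmap$probeset, , drop = FALSE], 1L, stats::IQR, type = 7)
  ord <- order(pmap$gene, -iqr, pmap$probeset)
  pmap <- pmap[ord, , drop = FALSE]
  keep <- pmap[!duplicated(pmap$gene), , drop = FALSE]
  out <- m[keep$probeset, , drop = FALSE]
  rownames(out) <- keep$gene
  out <- out[order(rownames(out)), , drop = FALSE]
  if (isPanel) {
    cd <- as.data.frame(colData(values))
    meta <- data.frame(sample_id = rownames(cd), cd, check.names = FALSE)
    ExpressionPanel(out, meta)
  } else out
}

#' One-to-one ortholog pairs from a homolog group table
#'
#' Only homolog groups containing exactly one gene of `taxonA` and exactly
#' one gene of `taxonB` yield a pair; any other multiplicity is skipped.
#'
#' @param table data.frame as returned by [readHomologTable()].
#' @param taxonA,taxonB taxon ids (coerced to character).
#' @return data.frame with columns `gene_a`, `gene_b`, one row per pair.
#' @export
oneToOneOrthologs <- function(table, taxonA, taxonB) {
  taxonA <- as.character(taxonA); taxonB <- as.character(taxonB)
  a <- table[table$taxon_id == taxonA, c("group_id", "gene_id")]
  b <- table[table$taxon_id == taxonB, c("group_id", "gene_id")]
  na <- table(a$group_id); nb <- table(b$group_id)
  ok <- intersect(names(na)[na == 1L], names(nb)[nb == 1L])
  a <- a[match(ok, a$group_id), ]
  b <- b[match(ok, b$group_id), ]
  out <- data.frame(gene_a = a$gene_id, gene_b = b$gene_id)
  if (anyDuplicated(out$gene_a) || anyDuplicated(out$gene_b))
    stop("internal error: ortholog pairing is not one-to-one")
  out[order(out$gene_a), , drop = FALSE]
}

#' Translate a ranking or gene set between taxa via one-to-one orthologs
#'
#' Gene ids are translated through the pair table; scores and ranks are
#' preserved. Genes without an ortholog pair are dropped and their count
#' reported via a warning.
#'
#' @param x an [AggregationResult-class], [RankedList-class] or character
#'   vector of gene ids.
#' @param pairs data.frame from [oneToOneOrthologs()].
#' @param direction `"a_to_b"` maps `gene_a` ids to `gene_b` ids;
#'   `"b_to_a"` the converse.
#' @return an object of the same type as `x` in the target taxon id space.
#' @export
mapRankingToTaxon <- function(x, pairs, direction = c("a_to_b", "b_to_a")) {
  direction <- match.arg(direction)
  from <- if (direction == "a_to_b") pairs$gene_a else pairs$gene_b
  to <- if (direction == "a_to_b") pairs$gene_b else pairs$gene_a
  translate <- function(ids) {
    idx <- match(ids, from)
    dropped <- sum(is.na(idx))
    if (dropped)
      warning(dropped, " gene(s) without an ortholog pair dropped")
    list(ids = to[idx[!is.na(idx)]], keep = !is.na(idx))
  }
  if (is.character(x)) {
    return(translate(x)$ids)
  }
  if (is(x, "RankedList")) {
    tr <- translate(names(x@ranks))
    r <- x@ranks[tr$keep]
    names(r) <- tr$ids
    # re-midrank so the reduced universe keeps the rank-sum invariant
    modulated <- translate(x@modulated)$ids
    return(RankedList(midrank(r, "lower"), modulated))
  }
  if (is(x, "AggregationResult")) {
    tr <- translate(names(x@rank))
    sc <- x@score[tr$keep]; names(sc) <- tr$ids
    rk <- x@rank[tr$keep]; names(rk) <- tr$ids
    p <- if (length(x@pvalue)) {
      v <- x@pvalue[tr$keep]; names(v) <- tr$ids; v
    } else numeric(0)
    q <- if (length(x@qvalue)) {
      v <- x@qvalue[tr$keep]; names(v) <- tr$ids; v
    } else numeric(0)
    return(AggregationResult(x@method, sc, midrank(rk, "lower"), p, q))
  }
  stop("unsupported input type for ortholog mapping")
}
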