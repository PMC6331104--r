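#' Gene-topic co-occurrence association testing
#'
#' For every gene with at least one annotated abstract, tests whether its
#' abstract set is enriched for topic abstracts with the one-tailed
#' (enrichment) Fisher's exact test against a declared abstract universe,
#' then BH-adjusts across tested genes. The universe is a count — the
#' background is the complete abstract collection, not only abstracts
#' annotated to genes — unless `restrictToAnnotated` is set, in which case
#' the background is the union of abstracts seen in `geneAbstracts` plus
#' the topic set.
#'
#' @param geneAbstracts named list mapping gene id to abstract ids (see
#'   [readGeneAbstractMap()]).
#' @param topic character vector of topic abstract ids.
#' @param universeSize total number of abstracts in the background.
#' @param restrictToAnnotated use the annotated-abstract union as
#'   background instead of the declared universe.
#' @return data.frame (one row per tested gene) with columns `gene_id`,
#'   `support` (abstracts shared with the topic), `gene_total`, `p`, `q`.
#' @export
geneTopicAssociation <- function(geneAbstracts, topic, universeSize,
                                 restrictToAnnotated = FALSE) {
  if (!length(geneAbstracts))
    stop("no gene-abstract annotations supplied")
  topic <- unique(as.character(topic))
  if (restrictToAnnotated) {
    bg <- unique(c(unlist(geneAbstracts, use.names = FALSE), topic))
    universeSize <- length(bg)
    topic <- intersect(topic, bg)
  }
  universeSize <- as.integer(universeSize)
  if (universeSize < length(topic))
    stop("universe smaller than the topic set")
  nAbs <- lengths(geneAbstracts)
  if (max(nAbs) > universeSize)
    stop("a gene has more abstracts than the declared universe")
  genes <- names(geneAbstracts)[nAbs > 0L]
  support <- vapply(geneAbstracts[genes],
                    function(a) length(intersect(a, topic)), integer(1))
  total <- lengths(geneAbstracts[genes])
  p <- mapply(fisherOneTailed, support, total,
              MoreArgs = list(topicTotal = length(topic),
                              universe = universeSize))
  q <- bhFDR(p)
  data.frame(gene_id = genes, support = unname(support),
             gene_total = unname(total), p = unname(p), q = unname(q),
             row.names = NULL)
}

#' Select literature candidate genes
#'
#' Applies the selection filters to an association table: FDR at or below
#' `fdrCut`, support by at least `minSupport` abstracts, and (when an
#' ortholog pair table is given) presence of a one-to-one ortholog. Both
#' the pre- and post-ortholog-filter decisions are reported.
#'
#' @param assoc data.frame from [geneTopicAssociation()].
#' @param fdrCut FDR threshold.
#' @param minSupport minimal number of supporting abstracts.
#' @param pairs optional ortholog pair table from [oneToOneOrthologs()];
#'   genes are matched against `gene_a`.
#' @return `assoc` with added logical columns `selected_pre_ortholog` and
#'   `selected`.
#' @export
selectCandidates <- function(assoc, fdrCut = 0.05, minSupport = 3L,
                             pairs = NULL) {
  pre <- assoc$q <= fdrCut & assoc$support >= minSupport
  paired <- if (is.null(pairs)) rep(TRUE, nrow(assoc))
            else assoc$gene_id %in% pairs$gene_a
  assoc$selected_pre_ortholog <- pre
  assoc$selected <- pre & paired
  assoc
}

#' Write a literature candidate table as TSV
#'
#' @param candidates data.frame from [selectCandidates()].
#' @param path output path.
#' @export
writeCandidates <- function(candidates, path) {
  out <- candidates[order(candidates$p, candidates$gene_id), ]
  for (cn in c("p", "q"))
    out[[cn]] <- format(out[[cn]], digits = 15, scientific = TRUE,
                        trim = TRUE)
  for (cn in c("selected_pre_ortholog", "selected"))
    if (cn %in% colnames(out)) out[[cn]] <- as.integer(out[[cn]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
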