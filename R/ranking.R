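#' Extended partial ranking of one compound's DE results
#'
#' Selected genes are ordered by decreasing R-squared of the adjusted
#' model, ties broken by increasing model p-value, residual ties by
#' midrank. All non-selected genes — those failing the global F-test,
#' those whose adjusted model kept no significant treatment coefficient,
#' and those below the R-squared floor — form a single tied bottom block.
#' By default the block carries the midrank of the remaining positions so
#' the rank sum stays `N(N+1)/2`; `bottomRank = "max"` assigns rank `N`
#' instead.
#'
#' @param results data.frame from [deAnalysis()] (one row per universe
#'   gene).
#' @param bottomRank `"midrank"` (default) or `"max"`.
#' @return a [RankedList-class].
#' @export
rankCompound <- function(results, bottomRank = c("midrank", "max")) {
  bottomRank <- match.arg(bottomRank)
  if (anyDuplicated(results$gene_id))
    stop("duplicate gene id in DE results")
  N <- nrow(results)
  sel <- which(results$selected)
  k <- length(sel)
  ranks <- rep(NA_real_, N)
  names(ranks) <- results$gene_id
  if (k > 0L) {
    r2 <- results$r2[sel]
    p <- results$adjusted_p[sel]
    # order by r2 desc, p asc; midrank for exact (r2, p) ties
    ord <- order(-r2, p)
    pos <- numeric(k)
    pos[ord] <- seq_len(k)
    tieKey <- paste(signif(r2, 12), signif(p, 12))
    ranks[sel] <- stats::ave(pos, tieKey, FUN = mean)
  }
  bottom <- setdiff(seq_len(N), sel)
  if (length(bottom))
    ranks[bottom] <- if (bottomRank == "midrank") (k + 1 + N) / 2 else N
  RankedList(ranks, results$gene_id[sel])
}

#' Normalized ranks of an extended partial ranking
#'
#' Divides every rank by the universe size, mapping into `(0, 1]`; the
#' order is unchanged. Uniform on `(0, 1]` under the null of an
#' uninformative list.
#'
#' @param rl a [RankedList-class].
#' @return named numeric vector of normalized ranks.
#' @export
normalizeRanks <- function(rl) {
  stopifnot(is(rl, "RankedList"))
  rl@ranks / length(rl@ranks)
}

#' Assemble a gene x compound matrix of normalized ranks
#'
#' @param lists named list of [RankedList-class] objects sharing one gene
#'   universe (one per compound).
#' @return numeric matrix, genes as rows, lists as columns, entries in
#'   `(0, 1]`.
#' @export
rankMatrix <- function(lists) {
  if (!length(lists)) stop("at least one ranked list is required")
  genes <- sort(geneIds(lists[[1L]]))
  cols <- lapply(lists, function(rl) {
    if (!setequal(geneIds(rl), genes))
      stop("all ranked lists must share one gene universe")
    normalizeRanks(rl)[genes]
  })
  m <- do.call(cbind, cols)
  rownames(m) <- genes
  if (is.null(colnames(m)) && !is.null(names(lists)))
    colnames(m) <- names(lists)
  m
}
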