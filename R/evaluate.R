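#' ROC curve and AUC of a ranking against a positive gene set
#'
#' Lower rank = more positive-like. Tied rank blocks are traversed as
#' single straight segments (the hallmark of extended partial rankings in
#' ROC space), and the trapezoidal area equals the Mann-Whitney statistic
#' with the midrank tie correction: ties between a positive and a negative
#' count one half.
#'
#' @param x an [AggregationResult-class], [RankedList-class] or named
#'   numeric rank vector.
#' @param positives character vector of positive gene ids (a proper,
#'   non-empty subset of the universe).
#' @return list with `points` (data.frame of `fpr`, `tpr`, starting at
#'   (0,0) and ending at (1,1)) and `auc`.
#' @export
rocAuc <- function(x, positives) {
  r <- if (is(x, "AggregationResult") || is(x, "RankedList"))
    geneRanks(x) else x
  if (is.null(names(r))) stop("ranks must be named by gene id")
  positives <- unique(positives)
  if (!all(positives %in% names(r)))
    stop("positives must be a subset of the ranked universe")
  nPos <- length(positives)
  nNeg <- length(r) - nPos
  if (nPos == 0L || nNeg == 0L)
    stop("positives must be a non-empty proper subset of the universe")
  isPos <- names(r) %in% positives
  grp <- factor(r, levels = sort(unique(r)))
  byBlock <- rowsum(cbind(as.numeric(isPos), as.numeric(!isPos)),
                    group = grp)
  posAt <- byBlock[, 1L]
  negAt <- byBlock[, 2L]
  tpr <- c(0, cumsum(posAt) / nPos)
  fpr <- c(0, cumsum(negAt) / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Spearman rank correlation between two gene rankings
#'
#' Pearson correlation of the two midrank vectors, with the p-value from
#' the standard large-sample t approximation. Genes are matched by name.
#'
#' @param a,b [AggregationResult-class]/[RankedList-class] objects or
#'   named rank vectors over the same universe.
#' @return list with `rho`, `p` and `n`.
#' @export
spearmanRanks <- function(a, b) {
  ra <- if (is(a, "AggregationResult") || is(a, "RankedList"))
    geneRanks(a) else a
  rb <- if (is(b, "AggregationResult") || is(b, "RankedList"))
    geneRanks(b) else b
  if (!setequal(names(ra), names(rb)))
    stop("rankings must share one gene universe")
  rb <- rb[names(ra)]
  ra <- midrank(ra, "lower")
  rb <- midrank(rb, "lower")
  n <- length(ra)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0)
    stop("constant ranking: Spearman correlation undefined")
  rho <- stats::cor(ra, rb)
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n)
}

combinedFrom <- function(score) {
  list(score = score, rank = midrank(score, "lower"))
}

#' Combine rankings by rank sum
#'
#' Adds the per-gene ranks of several aggregated rankings and re-ranks by
#' the sum (ascending); genes high in the combined list changed
#' consistently across all inputs.
#'
#' @param rankings list of [AggregationResult-class] objects (or named
#'   rank vectors) over one universe.
#' @return list with named vectors `score` (the rank sum) and `rank`.
#' @export
combineSum <- function(rankings) {
  if (!length(rankings)) stop("at least one ranking is required")
  vecs <- lapply(rankings, function(x)
    if (is(x, "AggregationResult") || is(x, "RankedList")) geneRanks(x)
    else x)
  genes <- sort(names(vecs[[1L]]))
  for (v in vecs)
    if (!setequal(names(v), genes))
      stop("all rankings must share one gene universe")
  score <- Reduce(`+`, lapply(vecs, function(v) v[genes]))
  names(score) <- genes
  combinedFrom(score)
}

#' Combine two rankings by rank difference
#'
#' Score = rank in `a` minus rank in `b`. The ascending head of the
#' combined list holds genes that changed in `a` but not in `b`; the
#' descending tail reads out the converse contrast.
#'
#' @param a,b [AggregationResult-class] objects (or named rank vectors)
#'   over one universe.
#' @return list with named vectors `score` (the rank difference) and
#'   `rank`.
#' @export
combineDiff <- function(a, b) {
  ra <- if (is(a, "AggregationResult") || is(a, "RankedList"))
    geneRanks(a) else a
  rb <- if (is(b, "AggregationResult") || is(b, "RankedList"))
    geneRanks(b) else b
  if (!setequal(names(ra), names(rb)))
    stop("rankings must share one gene universe")
  genes <- sort(names(ra))
  score <- ra[genes] - rb[genes]
  names(score) <- genes
  combinedFrom(score)
}

#' Best-ranked genes of a ranking
#'
#' Returns the `k` best-ranked genes; a tied block straddling the cut is
#' included entirely, and the realized size is reported as an attribute
#' and, when it differs from `k`, via a message.
#'
#' @param x an [AggregationResult-class], [RankedList-class], named rank
#'   vector, or a `combine*()` result.
#' @param k nominal list size, `1 <= k <= N`.
#' @return character vector of gene ids with attribute `realizedSize`.
#' @export
topK <- function(x, k) {
  r <- if (is(x, "AggregationResult") || is(x, "RankedList"))
    geneRanks(x)
  else if (is.list(x) && !is.null(x$rank)) x$rank
  else x
  N <- length(r)
  if (k < 1 || k > N) stop("'k' must lie in [1, N]")
  cutoff <- sort(r)[k]
  genes <- names(r)[r <= cutoff]
  genes <- genes[order(r[genes], genes)]
  if (length(genes) != k)
    message("tie block at the boundary: realized size ", length(genes),
            " (requested ", k, ")")
  attr(genes, "realizedSize") <- length(genes)
  genes
}

#' Write ROC points as TSV
#'
#' @param roc result of [rocAuc()].
#' @param path output path.
#' @export
writeRoc <- function(roc, path) {
  df <- data.frame(fpr = format(roc$points$fpr, digits = 15, trim = TRUE),
                   tpr = format(roc$points$tpr, digits = 15, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
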