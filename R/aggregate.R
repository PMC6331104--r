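#' Parameters of the Bayesian iterative rank aggregation (BIRRA)
#'
#' @param bins number of cumulative rank bins.
#' @param maxIter maximal number of reweighting iterations.
#' @param prior prior probability of the positive (signal) class.
#' @param pseudoCount additive smoothing count for the Bayes factors.
#' @return a validated `BirraParams` list.
#' @export
birraParams <- function(bins = 50L, maxIter = 10L, prior = 0.05,
                        pseudoCount = 1) {
  if (bins < 2L) stop("bins must be >= 2")
  if (maxIter < 1L) stop("maxIter must be >= 1")
  if (prior <= 0 || prior >= 1) stop("prior must be in (0, 1)")
  structure(list(bins = as.integer(bins), maxIter = as.integer(maxIter),
                 prior = prior, pseudoCount = pseudoCount),
            class = "BirraParams")
}

checkRankMatrix <- function(M) {
  if (is.null(dim(M)) || ncol(M) < 1L)
    stop("a gene x list rank matrix with at least one list is required")
  if (is.null(rownames(M)))
    stop("rank matrix must have gene ids as rownames")
  if (any(M <= 0 | M > 1))
    stop("normalized ranks must lie in (0, 1]")
  invisible(M)
}

aggResult <- function(method, score, better = c("lower", "higher"),
                      pvalue = numeric(0), qvalue = numeric(0)) {
  better <- match.arg(better)
  rk <- midrank(score, if (better == "lower") "lower" else "higher")
  names(rk) <- names(score)
  AggregationResult(method, score, rk, pvalue, qvalue)
}

#' MEAN aggregation: average of normalized ranks
#'
#' Scores each gene by the mean of its normalized ranks across lists;
#' significance comes from the exact Irwin-Hall distribution of a sum of
#' iid uniforms ([irwinHallCDF()]), BH-adjusted across genes. The
#' adjustment is monotone, so the final ordering equals ordering by the
#' mean itself.
#'
#' @param M gene x list matrix of normalized ranks (see [rankMatrix()]).
#' @return an [AggregationResult-class] with p- and q-values.
#' @export
aggregateMean <- function(M) {
  checkRankMatrix(M)
  m <- ncol(M)
  score <- rowMeans(M)
  p <- irwinHallCDF(rowSums(M), m)
  names(p) <- rownames(M)
  q <- bhFDR(p)
  names(q) <- rownames(M)
  aggResult("MEAN", score, "lower", p, q)
}

#' NC aggregation: number of compounds modulating the gene
#'
#' @param lists named list of [RankedList-class] objects (the `modulated`
#'   sets are counted).
#' @return an [AggregationResult-class]; score = modulation count, higher
#'   is better.
#' @export
aggregateNC <- function(lists) {
  if (!length(lists)) stop("at least one ranked list is required")
  genes <- sort(geneIds(lists[[1L]]))
  counts <- rowSums(vapply(lists, function(rl) genes %in% modulated(rl),
                           logical(length(genes))))
  names(counts) <- genes
  aggResult("NC", counts, "higher")
}

#' RRA: robust rank aggregation by beta order statistics
#'
#' For each gene the m normalized ranks are sorted ascending and the k-th
#' is compared to the null Beta(k, m-k+1) law of the k-th order statistic
#' of m iid uniforms; the minimum of the m tail probabilities, Bonferroni-
#' corrected by m, is the gene score (a p-value-like quantity, smaller =
#' stronger). Scores are BH-adjusted across genes for reporting; the
#' ordering is unchanged by the adjustment.
#'
#' @param M gene x list matrix of normalized ranks.
#' @return an [AggregationResult-class] with p- (the score) and q-values.
#' @export
aggregateRRA <- function(M) {
  checkRankMatrix(M)
  m <- ncol(M)
  sorted <- t(apply(M, 1L, sort))
  if (m == 1L) sorted <- matrix(sorted, ncol = 1L)
  pk <- vapply(seq_len(m),
               function(k) betaOrderCDF(sorted[, k], k, m),
               numeric(nrow(M)))
  if (nrow(M) == 1L) pk <- matrix(pk, nrow = 1L)
  rho <- apply(pk, 1L, min)
  score <- pmin(1, m * rho)
  names(score) <- rownames(M)
  q <- bhFDR(score)
  names(q) <- rownames(M)
  aggResult("RRA", score, "lower", score, q)
}

# P(U_(1) <= r_1, ..., U_(m) <= r_m) for m iid uniforms, r sorted
# ascending: classical recursion V_k = sum_i (-1)^(i-1) V_{k-i}
# r_{m-k+1}^i / i!, joint probability = m! V_m.
jointOrderProb <- function(r) {
  m <- length(r)
  if (m > 60L)
    stop("joint order-statistic recursion limited to m <= 60")
  V <- c(1, numeric(m))
  for (k in seq_len(m)) {
    i <- seq_len(k)
    V[k + 1L] <- sum((-1)^(i - 1) * V[k - i + 1L] *
                       r[m - k + 1L]^i / factorial(i))
  }
  min(max(exp(lgamma(m + 1)) * V[m + 1L], 0), 1)
}

#' STUART aggregation: joint order-statistic probability
#'
#' Scores each gene by `Q(r) = P(U_(1) <= r_(1), ..., U_(m) <= r_(m))`,
#' the probability that all m uniform order statistics fall below the
#' gene's sorted normalized ranks, computed by the exact joint recursion.
#' Smaller Q means the gene sits higher across lists than chance allows.
#'
#' @param M gene x list matrix of normalized ranks.
#' @param scaleFactorial multiply Q by an additional `m!` (a convention
#'   used by some implementations); the ordering is invariant to it.
#' @return an [AggregationResult-class]; score = Q, lower is better.
#' @export
aggregateStuart <- function(M, scaleFactorial = FALSE) {
  checkRankMatrix(M)
  score <- apply(M, 1L, function(r) jointOrderProb(sort(r)))
  if (scaleFactorial) score <- score * exp(lgamma(ncol(M) + 1))
  names(score) <- rownames(M)
  aggResult("STUART", score, "lower")
}

#' BIRRA: Bayesian iterative rank aggregation
#'
#' Starts from the mean-rank consensus, declares the top `prior * N` genes
#' putative positives, estimates for every list and cumulative rank bin a
#' smoothed Bayes factor (positives vs negatives enrichment in the bin),
#' monotonizes the log Bayes factors to be non-increasing with bin depth,
#' rescores every gene by the sum over lists of the log Bayes factor of
#' its bin, and re-ranks. Iterates until the rank vector is unchanged or
#' `maxIter` is reached.
#'
#' @param M gene x list matrix of normalized ranks.
#' @param params a [birraParams()] object.
#' @return an [AggregationResult-class]; score = summed log Bayes factor,
#'   higher is better.
#' @export
aggregateBIRRA <- function(M, params = birraParams()) {
  checkRankMatrix(M)
  N <- nrow(M)
  m <- ncol(M)
  B <- params$bins
  if (params$prior * N < 1) stop("prior * N must be at least 1")
  nPos <- ceiling(params$prior * N)
  pc <- params$pseudoCount
  binOf <- matrix(pmin(pmax(ceiling(M * B), 1L), B), nrow = N)

  aggRank <- midrank(rowMeans(M), "lower")
  score <- -rowMeans(M)
  for (iter in seq_len(params$maxIter)) {
    pos <- aggRank <= sort(aggRank)[nPos]  # putative positive set
    logBF <- matrix(0, nrow = B, ncol = m)
    for (c in seq_len(m)) {
      posBin <- cumsum(tabulate(binOf[pos, c], nbins = B))
      allBin <- cumsum(tabulate(binOf[, c], nbins = B))
      negBin <- allBin - posBin
      bf <- ((posBin + pc) / (nPos + pc)) /
        ((negBin + pc) / (N - nPos + pc))
      lb <- log(bf)
      logBF[, c] <- rev(cummax(rev(lb)))  # non-increasing with bin depth
    }
    score <- vapply(seq_len(N), function(g)
      sum(logBF[cbind(binOf[g, ], seq_len(m))]), numeric(1))
    newRank <- midrank(score, "higher")
    if (isTRUE(all.equal(unname(newRank), unname(aggRank),
                         tolerance = 1e-12))) {
      aggRank <- newRank
      break
    }
    aggRank <- newRank
  }
  names(score) <- rownames(M)
  aggResult("BIRRA", score, "higher")
}

#' AR aggregation: median of the five aggregated ranks
#'
#' @param results list of the five [AggregationResult-class] objects
#'   (MEAN, NC, RRA, STUART, BIRRA) over one universe, in any order.
#' @return an [AggregationResult-class]; score = per-gene median rank,
#'   lower is better.
#' @export
aggregateAR <- function(results) {
  need <- c("MEAN", "NC", "RRA", "STUART", "BIRRA")
  have <- vapply(results, rankMethod, character(1))
  miss <- setdiff(need, have)
  if (length(miss))
    stop("missing aggregation result(s) for AR: ",
         paste(miss, collapse = ", "))
  results <- results[match(need, have)]
  genes <- sort(geneIds(results[[1L]]))
  rk <- vapply(results, function(r) geneRanks(r)[genes],
               numeric(length(genes)))
  score <- apply(rk, 1L, stats::median)
  names(score) <- genes
  aggResult("AR", score, "lower")
}

#' Run all six aggregation methods on a set of compound rankings
#'
#' @param lists named list of [RankedList-class] objects, one per
#'   compound.
#' @param birra a [birraParams()] object.
#' @param scaleFactorial passed to [aggregateStuart()].
#' @return named list of six [AggregationResult-class] objects (MEAN, NC,
#'   RRA, STUART, BIRRA, AR).
#' @export
aggregateAll <- function(lists, birra = birraParams(),
                         scaleFactorial = FALSE) {
  M <- rankMatrix(lists)
  res <- list(MEAN = aggregateMean(M), NC = aggregateNC(lists),
              RRA = aggregateRRA(M),
              STUART = aggregateStuart(M, scaleFactorial),
              BIRRA = aggregateBIRRA(M, birra))
  res$AR <- aggregateAR(res)
  res
}

#' Write all aggregation results as one wide TSV
#'
#' One row per gene, with `score_<method>` and `rank_<method>` column
#' pairs for every method present; rows sorted by the last method's rank.
#'
#' @param results named list of [AggregationResult-class] objects.
#' @param path output path.
#' @export
writeCombinedRankings <- function(results, path) {
  genes <- sort(geneIds(results[[1L]]))
  df <- data.frame(gene_id = genes)
  for (nm in names(results)) {
    r <- results[[nm]]
    df[[paste0("score_", nm)]] <- format(geneScores(r)[genes],
                                         digits = 15, scientific = TRUE,
                                         trim = TRUE)
    df[[paste0("rank_", nm)]] <- format(geneRanks(r)[genes], digits = 15,
                                        trim = TRUE)
  }
  last <- results[[length(results)]]
  df <- df[order(geneRanks(last)[genes], genes), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
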