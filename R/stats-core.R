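#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment of a vector of p-values controlling the expected
#' fraction of false discoveries. Thin validated front-end to
#' [stats::p.adjust()] with `method = "BH"`; input order is preserved.
#'
#' @param p numeric vector of p-values, all in `[0, 1]`.
#' @return numeric vector of adjusted values (q-values), same length and
#'   order as `p`.
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhFDR <- function(p) {
  if (!is.numeric(p) || length(p) == 0L)
    stop("'p' must be a non-empty numeric vector")
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] and contain no NA")
  stats::p.adjust(p, method = "BH")
}

#' One-tailed Fisher's exact test for gene-topic enrichment
#'
#' Upper (enrichment) tail of the hypergeometric distribution:
#' the probability of observing at least `a` abstracts that are both linked
#' to the gene and members of the topic set, given the marginal counts.
#'
#' @param a overlap count (abstracts linked to the gene AND in the topic).
#' @param geneTotal number of abstracts linked to the gene.
#' @param topicTotal number of abstracts in the topic set.
#' @param universe total number of abstracts in the background.
#' @return the enrichment p-value `P(X >= a)`.
#' @examples
#' fisherOneTailed(3, 5, 13, 1000)
#' @export
fisherOneTailed <- function(a, geneTotal, topicTotal, universe) {
  counts <- c(a = a, geneTotal = geneTotal, topicTotal = topicTotal,
              universe = universe)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts)))
    stop("contingency counts must be non-negative integers")
  if (a > min(geneTotal, topicTotal))
    stop("'a' cannot exceed min(geneTotal, topicTotal)")
  if (geneTotal > universe || topicTotal > universe)
    stop("marginal totals cannot exceed the universe size")
  # P(X >= a) with X ~ Hypergeometric(universe, topicTotal, geneTotal)
  stats::phyper(a - 1, topicTotal, universe - topicTotal, geneTotal,
                lower.tail = FALSE)
}

#' CDF of a uniform order statistic
#'
#' `P(U_(k) <= r)` for the k-th order statistic of `m` iid Uniform(0,1)
#' variables, i.e. the Beta(k, m - k + 1) distribution function. This is
#' the null model the RRA score compares observed normalized ranks against.
#'
#' @param r normalized rank(s) in `[0, 1]` (vectorized).
#' @param k order index, `1 <= k <= m`.
#' @param m number of lists.
#' @return probability vector of the same length as `r`.
#' @examples
#' betaOrderCDF(0.1, 1, 3)  # 1 - 0.9^3
#' @export
betaOrderCDF <- function(r, k, m) {
  if (length(k) != 1L || length(m) != 1L || k < 1 || k > m)
    stop("'k' must satisfy 1 <= k <= m")
  if (any(r < 0 | r > 1, na.rm = TRUE))
    stop("'r' must lie in [0, 1]")
  stats::pbeta(r, k, m - k + 1)
}

#' Irwin-Hall CDF for a sum of iid uniforms
#'
#' Distribution function of `S = U_1 + ... + U_m` with iid Uniform(0,1)
#' terms, used to attach a significance value to the mean of normalized
#' ranks. Exact alternating-sum formula for `m <= 50`; for larger `m` the
#' normal approximation `N(m/2, m/12)` is used.
#'
#' @param s observed sum, `0 <= s <= m` (vectorized).
#' @param m number of uniform terms.
#' @return `P(S <= s)`.
#' @examples
#' irwinHallCDF(0.5, 2)  # s^2/2 = 0.125
#' @export
irwinHallCDF <- function(s, m) {
  if (length(m) != 1L || m < 1 || m != floor(m))
    stop("'m' must be a positive integer")
  if (any(s < 0 | s > m, na.rm = TRUE))
    stop("'s' must lie in [0, m]")
  if (m > 50L)
    return(stats::pnorm(s, mean = m / 2, sd = sqrt(m / 12)))
  vapply(s, function(si) {
    j <- 0:floor(si)
    # sum_j (-1)^j C(m,j) (s-j)^m / m!, accumulated in log space termwise
    terms <- exp(lchoose(m, j) + m * log(pmax(si - j, 0)) - lgamma(m + 1))
    val <- sum(terms * (-1)^j)
    min(max(val, 0), 1)
  }, numeric(1))
}

#' Midranks with explicit tie handling
#'
#' Ranks a score vector so that tied values receive the average of the
#' positions they span (rank sum is always `N(N+1)/2`). Rank 1 is the best
#' score under the chosen direction.
#'
#' @param scores numeric vector of finite scores.
#' @param direction `"higher"` if larger scores are better, `"lower"` if
#'   smaller scores are better.
#' @return numeric vector of midranks in `[1, N]`.
#' @examples
#' midrank(c(10, 8, 8, 2), "higher")
#' @export
midrank <- function(scores, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  if (length(scores) == 0L)
    stop("'scores' must be non-empty")
  if (!is.numeric(scores) || anyNA(scores) || any(!is.finite(scores)))
    stop("'scores' must be finite and free of NA")
  x <- if (direction == "higher") -scores else scores
  rank(x, ties.method = "average")
}
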