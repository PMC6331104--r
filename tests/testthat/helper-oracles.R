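# Independent oracles and small fixture builders shared across tests.

# Brute-force Benjamini-Hochberg step-up, written directly from the
# definition: q_(i) = min_{j >= i} min(1, m p_(j) / j), mapped back.
bhStepUpOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Hypergeometric upper tail P(X >= a) by explicit enumeration of the
# probability mass over all attainable overlap counts.
hyperTailOracle <- function(a, geneTotal, topicTotal, universe) {
  kmax <- min(geneTotal, topicTotal)
  kmin <- max(0L, geneTotal + topicTotal - universe)
  k <- kmin:kmax
  mass <- choose(topicTotal, k) * choose(universe - topicTotal,
                                         geneTotal - k) /
    choose(universe, geneTotal)
  sum(mass[k >= a])
}

# Sort the rows of a matrix (fast path for Monte-Carlo oracles).
rowSort <- function(M) {
  matrix(M[order(row(M), M)], ncol = ncol(M), byrow = TRUE)
}

# A small deterministic expression panel fixture: 4 timepoints x 4 dose
# groups x `reps` replicates for one compound, all-noise unless a shift
# function is supplied.
makePanelFixture <- function(nGenes = 50, reps = 3, seed = 101,
                             shiftFun = NULL, compound = "cpdX") {
  set.seed(seed)
  grid <- expand.grid(dose = c("control", "low", "middle", "high"),
                      time = c(3, 9, 12, 24), replicate = seq_len(reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  genes <- sprintf("g%03d", seq_len(nGenes))
  m <- matrix(8 + rnorm(nGenes * nrow(grid), 0, 0.5), nrow = nGenes,
              dimnames = list(genes, sprintf("s%02d", seq_len(nrow(grid)))))
  if (!is.null(shiftFun))
    m <- m + shiftFun(grid, nGenes)
  meta <- data.frame(sample_id = colnames(m), compound = compound,
                     dose = grid$dose, time = grid$time,
                     replicate = grid$replicate, system = "TST")
  ExpressionPanel(m, meta)
}

# Random DEResult table with arbitrary selection/tie structure, for
# rank-construction property tests.
makeDEFixture <- function(N, seed) {
  set.seed(seed)
  nSel <- sample(0:N, 1)
  sel <- sample(N, nSel)
  r2 <- rep(NA_real_, N)
  p <- rep(NA_real_, N)
  # coarse grid forces plenty of exact ties
  r2[sel] <- sample(seq(0.6, 0.95, by = 0.05), nSel, replace = TRUE)
  p[sel] <- sample(c(1e-5, 1e-4, 1e-3), nSel, replace = TRUE)
  data.frame(gene_id = sprintf("g%04d", seq_len(N)),
             passed_global = seq_len(N) %in% sel,
             global_q = ifelse(seq_len(N) %in% sel, 0.001, 0.5),
             adjusted_p = p, r2 = r2, n_coef = 16,
             has_significant_coef = seq_len(N) %in% sel,
             selected = seq_len(N) %in% sel)
}

# Planted rank matrix used by the aggregation recovery properties:
# `nPlanted` genes draw Beta(1, 25) normalized ranks in `goodLists` of the
# m lists, everything else is uniform.
makePlantedMatrix <- function(N = 1000, m = 10, nPlanted = 50,
                              goodLists = 8, seed = 7) {
  set.seed(seed)
  M <- matrix(runif(N * m), N, m,
              dimnames = list(sprintf("g%04d", seq_len(N)), NULL))
  planted <- sprintf("g%04d", seq_len(nPlanted))
  for (c in seq_len(goodLists))
    M[planted, c] <- rbeta(nPlanted, 1, 25)
  M[M == 0] <- .Machine$double.eps
  list(M = M, planted = planted)
}
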