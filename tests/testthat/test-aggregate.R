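mkM <- function(x, genes = sprintf("g%02d", seq_len(nrow(x)))) {
  rownames(x) <- genes
  x
}

test_that("MEAN aggregation scores and Irwin-Hall p-values agree", {
  M <- mkM(rbind(c(0.1, 0.2, 0.3), c(0.5, 0.5, 0.5), c(0.9, 0.8, 0.7)))
  r <- aggregateMean(M)
  expect_equal(unname(geneScores(r)), c(0.2, 0.5, 0.8))
  expect_equal(unname(geneRanks(r)), c(1, 2, 3))
  M2 <- mkM(rbind(c(0.2, 0.3), c(0.9, 0.9)))
  r2 <- aggregateMean(M2)
  expect_equal(unname(genePValues(r2)[1]), irwinHallCDF(0.5, 2))
  expect_equal(unname(genePValues(r2)[1]), 0.125)
  # identical rows: all genes tied at (N+1)/2
  M3 <- mkM(matrix(0.4, 5, 3))
  expect_equal(unname(geneRanks(aggregateMean(M3))), rep(3, 5))
  expect_error(aggregateMean(matrix(numeric(0), 0, 0)), "rank matrix")
})

test_that("NC aggregation counts modulating compounds", {
  des <- lapply(1:5, function(s) makeDEFixture(30, seed = s + 70))
  lists <- lapply(des, rankCompound)
  r <- aggregateNC(lists)
  counts <- vapply(sprintf("g%04d", 1:30), function(g)
    sum(vapply(lists, function(rl) g %in% modulated(rl), logical(1))),
    numeric(1))
  expect_equal(geneScores(r)[names(counts)], counts)
  better <- names(sort(counts, decreasing = TRUE))
  expect_lte(geneRanks(r)[better[1]], geneRanks(r)[better[15]])
  # nobody modulated: all tied
  empty <- lapply(lists, function(rl)
    RankedList(setNames(rep((30 + 1) / 2, 30), geneIds(rl))))
  expect_equal(unname(geneRanks(aggregateNC(empty))), rep(15.5, 30))
})

test_that("RRA reproduces the closed-form beta order-statistic score", {
  M <- mkM(matrix(c(0.1, 0.2, 0.3), 1))
  r <- aggregateRRA(M)
  # p_k = (0.271, 0.104, 0.027); rho = 0.027; score = 3 * 0.027
  expect_equal(unname(geneScores(r)), 3 * pbeta(0.3, 3, 1),
               tolerance = 1e-12)
  expect_equal(unname(geneScores(r)), 0.081, tolerance = 1e-12)
  expect_equal(unname(geneScores(aggregateRRA(mkM(matrix(0.25, 1))))),
               0.25)
  expect_equal(unname(geneScores(aggregateRRA(mkM(matrix(1, 1, 3))))), 1)
})

test_that("STUART equals the joint order-statistic probability", {
  expect_equal(unname(geneScores(aggregateStuart(mkM(matrix(0.3, 1))))),
               0.3)
  expect_equal(unname(geneScores(aggregateStuart(
    mkM(matrix(c(0.1, 0.2), 1))))), 0.2^2 - 0.1^2, tolerance = 1e-12)
  expect_equal(unname(geneScores(aggregateStuart(
    mkM(matrix(1, 1, 4))))), 1)
  # factorial scaling changes scores but not the ordering
  pm <- makePlantedMatrix(N = 60, m = 4, nPlanted = 8, goodLists = 3,
                          seed = 71)
  a <- aggregateStuart(pm$M)
  b <- aggregateStuart(pm$M, scaleFactorial = TRUE)
  expect_equal(geneRanks(a), geneRanks(b))
  expect_equal(geneScores(b), geneScores(a) * factorial(4))
})

test_that("STUART joint probability matches Monte-Carlo dominance", {
  set.seed(72)
  n <- 2e5
  for (m in 2:4) {
    S <- rowSort(matrix(runif(n * m), n, m))
    for (rep in 1:3) {
      r <- sort(runif(m, 0.1, 0.9))
      q <- toxrank:::jointOrderProb(r)
      emp <- mean(rowSums(S <= rep(r, each = n)) == m)
      se <- sqrt(max(q * (1 - q), 1e-12) / n)
      expect_lt(abs(q - emp), 4 * se + 1e-10)
    }
  }
})

test_that("BIRRA preserves single-list order and recovers planted genes", {
  set.seed(73)
  M <- mkM(matrix(sample(1:40) / 40, ncol = 1))
  r <- aggregateBIRRA(M, birraParams(bins = 10, prior = 0.1))
  # monotone Bayes factors preserve the input order weakly: genes sharing
  # a bin tie, but no gene may overtake a better-ranked one
  expect_true(all(diff(geneRanks(r)[order(M[, 1])]) >= 0))
  pm <- makePlantedMatrix(seed = 74)
  rb <- aggregateBIRRA(pm$M)
  top100 <- topK(rb, 100)
  expect_gte(length(intersect(top100, pm$planted)) /
               length(pm$planted), 0.9)
  expect_error(aggregateBIRRA(pm$M, birraParams(prior = 1e-9)),
               "prior")
})

test_that("AR takes the median of the five method ranks", {
  lists <- lapply(1:5, function(s) rankCompound(makeDEFixture(100, s + 80)))
  names(lists) <- paste0("c", 1:5)
  res <- aggregateAll(lists)
  genes <- geneIds(res$AR)
  med <- apply(vapply(res[c("MEAN", "NC", "RRA", "STUART", "BIRRA")],
                      function(r) geneRanks(r)[genes], numeric(100)),
               1, median)
  expect_equal(geneScores(res$AR)[genes], med)
  # idempotence: five identical inputs give back the same order
  same <- lapply(1:5, function(i) res$RRA)
  for (i in seq_along(same)) same[[i]]@method <-
      c("MEAN", "NC", "RRA", "STUART", "BIRRA")[i]
  arSame <- aggregateAR(same)
  expect_equal(order(geneRanks(arSame)), order(geneRanks(res$RRA)))
  expect_error(aggregateAR(res[c("MEAN", "NC", "RRA", "STUART")]),
               "BIRRA")
})

test_that("aggregation is equivariant to gene permutation and list order", {
  pm <- makePlantedMatrix(N = 80, m = 6, nPlanted = 10, goodLists = 4,
                          seed = 76)
  M <- pm$M
  set.seed(77)
  perm <- sample(nrow(M))
  shuf <- sample(ncol(M))
  for (fn in list(aggregateMean, aggregateRRA, aggregateStuart,
                  function(m) aggregateBIRRA(m, birraParams(bins = 20)))) {
    base <- fn(M)
    permuted <- fn(M[perm, ])
    expect_equal(geneRanks(permuted)[geneIds(base)], geneRanks(base))
    reordered <- fn(M[, shuf])
    expect_equal(geneRanks(reordered), geneRanks(base))
  }
})

test_that("planted-signal recovery separates methods as expected", {
  pm <- makePlantedMatrix(seed = 78)
  res <- list(MEAN = aggregateMean(pm$M), RRA = aggregateRRA(pm$M),
              STUART = aggregateStuart(pm$M),
              BIRRA = aggregateBIRRA(pm$M))
  aucs <- vapply(res, function(r) rocAuc(r, pm$planted)$auc, numeric(1))
  expect_gte(aucs["RRA"], 0.95)
  expect_gte(aucs["STUART"], 0.95)
  expect_gt(aucs["MEAN"], 0.5)
  expect_lte(aucs["MEAN"], max(aucs))
})
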