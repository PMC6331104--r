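test_that("design matrix has the documented column structure", {
  panel <- makePanelFixture(nGenes = 2, reps = 2, seed = 51)
  cd <- SummarizedExperiment::colData(panel)
  d <- buildDesign(cd, 3)
  expect_equal(d$nCoef, 16)  # 4 time columns + 3 dose blocks of 4
  expect_equal(sum(d$groupCols), 12)
  expect_equal(d$degree, 3)
  # degree capped by the number of distinct timepoints
  cd2 <- as.data.frame(cd)[cd$time %in% c(3, 24), ]
  d2 <- buildDesign(cd2, 3)
  expect_equal(d2$degree, 1)
  expect_equal(d2$nCoef, 2 + 3 * 2)
  # a missing dose arm contributes no columns
  cd3 <- as.data.frame(cd)[cd$dose != "low", ]
  d3 <- buildDesign(cd3, 3)
  expect_equal(d3$nCoef, 4 + 2 * 4)
  expect_error(buildDesign(data.frame(dose = "high", time = 1:4)),
               "control")
})

test_that("global F-test handles degenerate and exact responses", {
  panel <- makePanelFixture(nGenes = 2, reps = 2, seed = 52)
  d <- buildDesign(SummarizedExperiment::colData(panel), 3)
  n <- nrow(d$X)
  expect_equal(fitGlobal(rep(5, n), d)$pValue, 1)
  exact <- fitGlobal(3 + 2 * d$X[, "high:time1"], d)
  expect_equal(exact$pValue, 0)
  expect_equal(exact$r2, 1)
})

test_that("global F-test p-values are uniform under the null", {
  panel <- makePanelFixture(nGenes = 500, reps = 2, seed = 53)
  d <- buildDesign(SummarizedExperiment::colData(panel), 3)
  Y <- SummarizedExperiment::assay(panel, "log2")
  p <- toxrank:::globalFPValues(Y, d$X)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  # the vectorized path agrees with the single-gene fit
  for (i in c(1, 250, 500))
    expect_equal(unname(p[i]), fitGlobal(Y[i, ], d)$pValue,
                 tolerance = 1e-10)
})

test_that("backward stepwise recovers a strong term and prunes noise", {
  panel <- makePanelFixture(nGenes = 2, reps = 3, seed = 54)
  d <- buildDesign(SummarizedExperiment::colData(panel), 3)
  alpha <- 0.05 / d$nCoef
  set.seed(55)
  hits <- 0
  for (i in 1:50) {
    y <- 5 + 10 * d$X[, "high"] + rnorm(nrow(d$X))  # 10 sigma effect
    sw <- backwardStepwise(y, d, alpha)
    hits <- hits + ("high" %in% sw$active && sw$hasGroupCoef)
  }
  expect_gte(hits, 49)
  # pure noise: intercept-only in the vast majority of fits
  nullOnly <- 0
  for (i in 1:500) {
    sw <- backwardStepwise(rnorm(nrow(d$X)), d, alpha)
    nullOnly <- nullOnly + (length(sw$active) == 1L)
  }
  expect_gte(nullOnly / 500, 0.93)
  # an already fully significant model is a fixed point (tiny noise so
  # every coefficient stays significant despite polynomial collinearity)
  yFull <- as.vector(d$X %*% c(1, rep(8, 15))) + rnorm(nrow(d$X), 0, 1e-3)
  swFull <- backwardStepwise(yFull, d, alpha)
  expect_setequal(swFull$active, colnames(d$X))
})

test_that("the DE screen recovers planted signal and stays null-calibrated", {
  sim <- simulatePanel(simulationConfig(nGenes = 1000, nCompounds = 2,
                                        nToxicCompounds = 1,
                                        nPlanted = 60, seed = 56))
  toxic <- sim$truth$toxicCompounds[1]
  de <- deAnalysis(sim$panels[[toxic]])
  hit <- sim$truth$responsive[[toxic]]
  # expected recovery is ~0.65 under these conditions; the bound sits two
  # binomial standard deviations below it for the ~35 responsive genes
  recovery <- mean(de$selected[de$gene_id %in% hit])
  expect_gte(recovery, 0.5)
  falseFrac <- mean(de$selected[!de$gene_id %in% hit])
  expect_lte(falseFrac, 2 * 0.01)
  # signal-free compound: selection bounded by twice the global FDR
  quiet <- setdiff(names(sim$panels), toxic)[1]
  deNull <- deAnalysis(sim$panels[[quiet]])
  expect_lte(mean(deNull$selected), 2 * 0.01)
  # selected implies passed_global, and R2 is within [0,1]
  expect_true(all(de$passed_global[de$selected]))
  expect_true(all(de$r2[de$selected] >= 0 & de$r2[de$selected] <= 1))
})

test_that("time drift shared by all groups is not selected", {
  drift <- function(grid, nGenes) {
    matrix(rep(0.15 * grid$time, each = nGenes), nrow = nGenes)
  }
  panel <- makePanelFixture(nGenes = 150, reps = 3, seed = 57,
                            shiftFun = drift)
  de <- deAnalysis(panel)
  # drift passes the global F-test but keeps no treatment coefficient
  # beyond stepwise chance retention (12 group coefficients at 0.05/16
  # each); the R2 filter cannot help since drift itself explains variance
  expect_gt(mean(de$passed_global), 0.9)
  expect_lte(mean(de$selected), 2 * 12 * 0.05 / 16)
})

test_that("DE output is deterministic for a fixed panel", {
  panel <- makePanelFixture(nGenes = 100, reps = 2, seed = 58)
  expect_identical(deAnalysis(panel), deAnalysis(panel))
})
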