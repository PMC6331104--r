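test_that("panel simulation is deterministic and validates its config", {
  cfg <- simulationConfig(nGenes = 60, nCompounds = 3,
                          nToxicCompounds = 2, nPlanted = 10, seed = 21)
  a <- simulatePanel(cfg)
  b <- simulatePanel(cfg)
  expect_identical(lapply(a$panels, SummarizedExperiment::assay, "log2"),
                   lapply(b$panels, SummarizedExperiment::assay, "log2"))
  expect_identical(a$truth, b$truth)
  # responsive subsets live inside the planted set; non-toxic are empty
  for (cpd in names(a$panels)) {
    if (cpd %in% a$truth$toxicCompounds)
      expect_true(all(a$truth$responsive[[cpd]] %in% a$truth$planted))
    else expect_length(a$truth$responsive[[cpd]], 0)
  }
  expect_error(simulationConfig(timepoints = 24), "two timepoints")
  expect_error(simulationConfig(replicates = 0), "replicate")
  expect_error(simulationConfig(nPlanted = 10, nGenes = 5), "nPlanted")
})

test_that("planted effect magnitude matches the configured size", {
  sim <- simulatePanel(simulationConfig(seed = 22))
  cfg <- simulationConfig(seed = 22)
  diffs <- c()
  for (cpd in sim$truth$toxicCompounds[1:4]) {
    panel <- sim$panels[[cpd]]
    cd <- SummarizedExperiment::colData(panel)
    hit <- sim$truth$responsive[[cpd]]
    late <- max(cd$time)
    hi <- cd$dose == "high" & cd$time == late
    ct <- cd$dose == "control" & cd$time == late
    Y <- SummarizedExperiment::assay(panel, "log2")
    diffs <- c(diffs, abs(rowMeans(Y[hit, hi]) - rowMeans(Y[hit, ct])))
  }
  expect_lt(abs(mean(diffs) - cfg$effectSize), 0.2 * cfg$effectSize)
})

test_that("zero effect size embeds planted genes in the null", {
  sim <- simulatePanel(simulationConfig(nGenes = 300, nCompounds = 1,
                                        nToxicCompounds = 1,
                                        nPlanted = 100, effectSize = 0,
                                        seed = 23))
  panel <- sim$panels[[1]]
  cd <- SummarizedExperiment::colData(panel)
  Y <- SummarizedExperiment::assay(panel, "log2")
  hit <- sim$truth$responsive[[1]]
  skip_if(length(hit) < 20)
  # two-sample t between high-dose and control means, per planted gene
  p <- apply(Y[hit, ], 1, function(y)
    t.test(y[cd$dose == "high"], y[cd$dose == "control"])$p.value)
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("literature simulation plants topic support and is seeded", {
  sim <- simulatePanel(simulationConfig(nGenes = 100, nCompounds = 2,
                                        nToxicCompounds = 2,
                                        nPlanted = 20, seed = 24))
  litA <- simulateLiterature(sim$truth, overlapFraction = 1,
                             universeSize = 5000, seed = 31,
                             backgroundTopicRate = 0)
  litB <- simulateLiterature(sim$truth, overlapFraction = 1,
                             universeSize = 5000, seed = 31,
                             backgroundTopicRate = 0)
  expect_identical(litA, litB)
  support <- vapply(litA$geneAbstracts,
                    function(a) length(intersect(a, litA$topic)),
                    integer(1))
  expect_true(all(support[sim$truth$planted] >= 3))
  expect_true(all(support[setdiff(sim$truth$genes,
                                  sim$truth$planted)] == 0))
  # overlapFraction 0: no gene receives preferential topic support
  lit0 <- simulateLiterature(sim$truth, overlapFraction = 0,
                             universeSize = 5000, seed = 32)
  s0 <- vapply(lit0$geneAbstracts,
               function(a) length(intersect(a, lit0$topic)), integer(1))
  expect_lt(mean(s0[sim$truth$planted]), 1.5)
  expect_error(simulateLiterature(sim$truth, universeSize = 5,
                                  seed = 1), "universe too small")
})
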