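test_that("ROC handles separation, midrank ties and full ties", {
  r <- setNames(c(1, 2, 3, 4, 5), paste0("g", 1:5))
  roc <- rocAuc(r, c("g1", "g2"))
  expect_equal(roc$auc, 1)
  expect_equal(unlist(roc$points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc$points[nrow(roc$points), ]),
               c(fpr = 1, tpr = 1))
  # midrank tie between a positive and a negative counts one half
  r2 <- setNames(c(1, 2.5, 2.5, 4), paste0("g", 1:4))
  expect_equal(rocAuc(r2, c("g1", "g2"))$auc, 3.5 / 4)
  # all tied: single diagonal, area one half
  r3 <- setNames(rep(2.5, 4), paste0("g", 1:4))
  roc3 <- rocAuc(r3, c("g1", "g3"))
  expect_equal(roc3$auc, 0.5)
  expect_equal(nrow(roc3$points), 2)
  expect_error(rocAuc(r, paste0("g", 1:5)), "proper subset")
  expect_error(rocAuc(r, character(0)), "proper subset")
})

test_that("AUC of a ranking and its reverse sum to one", {
  set.seed(111)
  for (i in 1:20) {
    N <- sample(10:150, 1)
    r <- setNames(midrank(sample(N, N, replace = TRUE), "lower"),
                  paste0("g", seq_len(N)))
    pos <- sample(names(r), sample(1:(N - 1), 1))
    fwd <- rocAuc(r, pos)$auc
    rev <- rocAuc(setNames(midrank(-r, "lower"), names(r)), pos)$auc
    expect_equal(fwd + rev, 1, tolerance = 1e-12)
  }
})

test_that("random rankings score near one half on average", {
  set.seed(112)
  N <- 300
  pos <- paste0("g", 1:30)
  aucs <- replicate(200, {
    r <- setNames(sample(N), paste0("g", seq_len(N)))
    rocAuc(r, pos)$auc
  })
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se)
})

test_that("Spearman correlation matches its definition and stats::cor.test", {
  a <- setNames(c(1, 2, 3), c("x", "y", "z"))
  expect_equal(spearmanRanks(a, a)$rho, 1)
  expect_equal(spearmanRanks(a, setNames(c(3, 2, 1), names(a)))$rho, -1)
  b <- setNames(c(2, 1, 3), names(a))
  expect_equal(spearmanRanks(a, b)$rho, 0.5)  # 1 - 6*2/(3*8)
  set.seed(113)
  x <- setNames(midrank(sample(50, 50, TRUE), "lower"), paste0("g", 1:50))
  y <- setNames(midrank(sample(50, 50, TRUE), "lower"), paste0("g", 1:50))
  mine <- spearmanRanks(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                   exact = FALSE))
  expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
  # symmetric, and invariant to a common strictly monotone transform
  expect_equal(spearmanRanks(y, x)$rho, mine$rho)
  expect_equal(spearmanRanks(exp(x / 10), exp(y / 10))$rho, mine$rho)
  expect_error(spearmanRanks(setNames(rep(1, 3), names(a)), a),
               "constant")
})

test_that("rank combination by sum and difference behaves as documented", {
  r1 <- setNames(c(10, 20, 30, 40), paste0("g", 1:4))
  r2 <- setNames(c(40, 30, 20, 10), paste0("g", 1:4))
  cs <- combineSum(list(r1, r1, r1, r1))
  expect_equal(unname(cs$score["g1"]), 40)
  expect_equal(order(cs$rank), order(r1))
  # exact reverses: everything ties
  both <- combineSum(list(r1, r2))
  expect_true(all(both$score == 50))
  expect_equal(unname(both$rank), rep(2.5, 4))
  cd <- combineDiff(r1, r2)
  expect_equal(unname(cd$score), c(-30, -10, 10, 30))
  swapped <- combineDiff(r2, r1)
  expect_equal(swapped$score, -cd$score)
  expect_equal(combineDiff(r1, r1)$score, setNames(rep(0, 4),
                                                   names(r1)))
  expect_error(combineDiff(r1, r2[-1]), "universe")
})

test_that("topK respects boundaries and includes straddling tie blocks", {
  r <- setNames(c(1, 2, 3, 4, 5), paste0("g", 1:5))
  expect_equal(topK(r, 2), c("g1", "g2"), ignore_attr = TRUE)
  expect_equal(length(topK(r, 5)), 5)
  rt <- setNames(c(1, 2.5, 2.5, 4), paste0("g", 1:4))
  expect_message(out <- topK(rt, 2), "realized size 3")
  expect_equal(attr(out, "realizedSize"), 3)
  expect_error(topK(r, 0), "k")
  expect_error(topK(r, 6), "k")
})
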