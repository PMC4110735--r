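toyGold <- function() {
  GoldStandard(c("A", "B", "C", "D"),
               rbind(c("A", "B"), c("A", "C"), c("B", "C")))
}

toyPred <- function(scores = c(.9, .8, .7, .6, .5, .4)) {
  data.frame(gene1 = c("A", "A", "A", "B", "B", "C"),
             gene2 = c("B", "C", "D", "C", "D", "D"),
             score = scores)
}

test_that("F-beta reduces to P when P equals R, and matches hand arithmetic", {
  for (b in c(0.5, 1, 2)) {
    expect_equal(fBeta(0.3, 0.3, b), 0.3)
    expect_equal(fBeta(1, 1, b), 1)
  }
  expect_equal(fBeta(1, 0.5, 0.5), 1.25 * 0.5 / (0.25 + 0.5))
  expect_equal(fBeta(0.5, 1, 2), 5 * 0.5 / (4 * 0.5 + 1))
  expect_warning(z <- fBeta(0, 0, 1), "undefined")
  expect_equal(z, 0)
  expect_error(fBeta(1.2, 0.5), "\\[0, 1\\]")
  expect_error(fBeta(0.5, 0.5, beta = -1), "beta")
})

test_that("curves on the 6-pair toy match hand-enumerated confusion tables", {
  pr <- prCurve(toyPred(), toyGold())
  expect_equal(pr$recall, c(0, 1, 2, 2, 3, 3, 3) / 3)
  expect_equal(pr$precision, c(1, 1, 1, 2/3, 3/4, 3/5, 1/2))
  roc <- rocCurve(toyPred(), toyGold())
  expect_equal(roc$fpr, c(0, 0, 0, 1, 1, 2, 3) / 3)
  expect_equal(roc$tpr, c(0, 1, 2, 2, 3, 3, 3) / 3)
  expect_equal(curveAuc(pr$recall, pr$precision), 65 / 72)
  expect_equal(curveAuc(roc$fpr, roc$tpr), 8 / 9)
})

test_that("toy areas agree with the pROC reference implementation", {
  labels <- c(1, 1, 0, 1, 0, 0)
  scores <- c(.9, .8, .7, .6, .5, .4)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  roc <- rocCurve(toyPred(scores), toyGold())
  expect_equal(curveAuc(roc$fpr, roc$tpr), ref)
})

test_that("perfect and inverted rankings bound the curves", {
  gold <- toyGold()
  perfect <- toyPred(c(1, 1, 0, 1, 0, 0))
  pr <- prCurve(perfect, gold)
  # precision is 1 at every recall level first reached (the final all-in
  # threshold only drops precision vertically at recall 1)
  expect_true(all(tapply(pr$precision, pr$recall, max) == 1))
  sc <- evaluateNetwork(perfect, gold)
  expect_equal(sc@aupr, 1)
  expect_equal(sc@auroc, 1)
  expect_equal(sc@fBetaMax, 1)
  inverted <- toyPred(c(0, 0, 1, 0, 1, 1))
  expect_lt(evaluateNetwork(inverted, gold)@auroc, 0.5)
})

test_that("trapezoid area handles simple shapes and rejects bad input", {
  expect_equal(curveAuc(c(0, 1), c(0, 1)), 0.5)
  expect_equal(curveAuc(c(0, 1), c(1, 1)), 1)
  expect_equal(curveAuc(data.frame(x = c(0, 0.5, 1), y = c(0, 1, 0))), 0.5)
  expect_error(curveAuc(1, 1), "2 points")
  expect_error(curveAuc(c(1, 0), c(0, 1)), "non-decreasing")
})

test_that("an empty prediction scores at the positive prevalence", {
  gold <- toyGold()
  empty <- toyPred(rep(0, 6))
  sc <- evaluateNetwork(empty, gold)
  prev <- 3 / 6
  expect_equal(sc@aupr, prev)
  expect_equal(sc@auroc, 0.5)
  # single threshold group: everything predicted, P = prevalence, R = 1
  expect_equal(sc@fBetaMax, fBeta(prev, 1, 0.5))
})

test_that("scores are invariant to strictly monotone transforms of confidence", {
  set.seed(21)
  gold <- toyGold()
  scores <- runif(6)
  a <- evaluateNetwork(toyPred(scores), gold)
  b <- evaluateNetwork(toyPred(exp(2 * scores)), gold)
  expect_equal(a@aupr, b@aupr)
  expect_equal(a@auroc, b@auroc)
  expect_equal(a@fBetaMax, b@fBetaMax)
})

test_that("network evaluation uses combined support and ignores edge sign", {
  set.seed(6)
  base <- 300 * exp(cumsum(rnorm(12, 0, 0.03)))
  em <- rbind(a = base, b = base + 5, c = 2 * mean(base) - base,
              d = cumsum(rnorm(12, 0, 200)))
  net <- buildNetwork(buildCorrelogram(edgeTransform(em)), 0.5)
  expect_equal(adjacency(net)["a", "c"], -1L)  # negative edge present
  gold <- GoldStandard(c("a", "b", "c", "d"),
                       rbind(c("a", "b"), c("a", "c"), c("b", "c")))
  sc <- evaluateNetwork(net, gold)
  expect_equal(sc@aupr, 1)
  expect_equal(sc@auroc, 1)
})

test_that("gene-universe mismatches raise a reconciliation error", {
  gold <- toyGold()
  bad <- data.frame(gene1 = "A", gene2 = "Zz", score = 1)
  expect_error(evaluateNetwork(bad, gold), "Zz")
  emptyGold <- GoldStandard(c("A", "B"), matrix(character(0), 0, 2))
  expect_error(evaluateNetwork(toyPred(), emptyGold), "no positive pairs")
})

test_that("random rankings concentrate AUROC near one half", {
  n <- 20
  genes <- sprintf("g%02d", 1:n)
  allPairs <- t(combn(genes, 2))
  set.seed(99)
  truth <- allPairs[sample(nrow(allPairs), 30), , drop = FALSE]
  gold <- GoldStandard(genes, truth)
  aucs <- vapply(1:25, function(s) {
    set.seed(1000 + s)
    pred <- data.frame(gene1 = allPairs[, 1], gene2 = allPairs[, 2],
                       score = runif(nrow(allPairs)))
    evaluateNetwork(pred, gold)@auroc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})
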