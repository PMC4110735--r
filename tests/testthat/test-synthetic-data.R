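test_that("base profiles are deterministic given the seed and non-degenerate", {
  for (style in c("fluctuating", "level")) {
    p1 <- makeBaseProfile(15, seed = 42, style = style)
    p2 <- makeBaseProfile(15, seed = 42, style = style)
    expect_identical(p1, p2)
    expect_false(identical(p1, makeBaseProfile(15, seed = 43, style = style)))
    expect_length(makeBaseProfile(3, seed = 1, style = style), 3)
    expect_true(all(diff(p1) != 0))
  }
  expect_error(makeBaseProfile(2, seed = 1), ">= 3")
})

test_that("noise-free member derivation follows the pattern definitions", {
  base <- makeBaseProfile(12, seed = 5, style = "level")
  expect_equal(deriveMember(base, "shifted", alpha = 5), base + 5)
  expect_equal(deriveMember(base, "scaled", betaFactor = 3), base * 3)
  inv <- deriveMember(base, "inverted")
  expect_equal(inv, 2 * mean(base) - base)
  expect_error(deriveMember(base, "sideways"), "kind")
  expect_error(deriveMember(base, "scaled", betaFactor = 0), "betaFactor")
})

test_that("regulation sequences transform as the pattern kinds dictate", {
  base <- makeBaseProfile(15, seed = 9, style = "level")
  regOf <- function(v) as.vector(regulations(edgeTransform(rbind(x = v))))
  r0 <- regOf(base)
  expect_identical(regOf(deriveMember(base, "shifted", alpha = 7)), r0)
  expect_identical(regOf(deriveMember(base, "scaled", betaFactor = 2)), r0)
  expect_identical(regOf(deriveMember(base, "inverted")), -r0)
  # scaled members keep the full representation, not only the signs
  expect_equal(angles(edgeTransform(rbind(x = base * 2))),
               angles(edgeTransform(rbind(x = base))), tolerance = 1e-12)
})

test_that("datasets are reproducible and truth structures consistent", {
  spec <- patternSpec(seed = 7)
  d1 <- generateDataset(spec)
  d2 <- generateDataset(spec)
  expect_identical(exprs(d1), exprs(d2))
  expect_identical(positivePairs(goldStandard(d1)),
                   positivePairs(goldStandard(d2)))
  expect_false(identical(exprs(d1),
                         exprs(generateDataset(patternSpec(seed = 8)))))
  # truth edges are exactly the within-module cliques
  lab <- moduleLabels(d1)
  expect_equal(nrow(positivePairs(goldStandard(d1))), 3 * choose(10, 2))
  p <- positivePairs(goldStandard(d1))
  expect_true(all(lab[p[, 1]] == lab[p[, 2]]))
  expect_true(all(lab[p[, 1]] > 0))
  # background genes carry no truth edges and no orientation flips
  bg <- names(lab)[lab == 0]
  expect_false(any(p %in% bg))
  expect_true(all(orientations(d1)[bg] == 1))
  # inverted module mixes orientations so both edge signs are planted
  ts <- truthSigns(d1)
  expect_setequal(unique(ts$sign), c(1, -1))
})

test_that("a noise-free dataset without background is recovered exactly", {
  ds <- generateDataset(patternSpec(seed = 11, noiseSd = 0,
                                    nBackgroundGenes = 0))
  net <- buildNetwork(buildCorrelogram(edgeTransform(exprs(ds)), tau = 20),
                      theta = 0.5)
  A <- adjacency(net)
  lab <- moduleLabels(ds)
  truth <- outer(lab, lab, function(x, y) x == y & x > 0)
  diag(truth) <- FALSE
  expect_identical(unname(A != 0), unname(truth))
  # recovered signs equal the planted orientation products
  ts <- outer(orientations(ds), orientations(ds))
  expect_true(all(A[A != 0] == ts[A != 0]))
})

test_that("background-only datasets stay nearly edge-free at theta 0.5", {
  ds <- generateDataset(patternSpec(nModules = 0, genesPerModule = 2,
                                    patternKinds = character(0),
                                    nBackgroundGenes = 30, seed = 13))
  net <- buildNetwork(buildCorrelogram(edgeTransform(exprs(ds))), 0.5)
  A <- adjacency(net)
  falseRate <- sum(A[upper.tri(A)] != 0) / choose(30, 2)
  expect_lt(falseRate, 0.02)
})

test_that("planted modules are recovered at tau 20, theta 0.5 under low noise", {
  stats <- vapply(1:8, recoveryStats, numeric(3))
  expect_gte(mean(stats["precision", ]), 0.9)
  expect_gte(mean(stats["recall", ]), 0.9)
  expect_gte(mean(stats["signAgreement", ]), 0.9)
})

test_that("recovery degrades monotonically as noise grows", {
  noises <- c(0, 50, 150, 300)
  fbar <- vapply(noises, function(ns) {
    st <- vapply(1:5, recoveryStats, numeric(3), noiseSd = ns)
    p <- mean(st["precision", ]); r <- mean(st["recall", ])
    2 * p * r / (p + r)
  }, 0)
  expect_true(all(diff(fbar) <= 0.02))   # non-increasing up to seed jitter
  expect_gt(fbar[1] - fbar[4], 0.3)      # and clearly degraded at high noise
})

test_that("mixed-kind members share part of the base and invert the rest", {
  spec <- patternSpec(nModules = 1, patternKinds = "mixed",
                      genesPerModule = 6, nBackgroundGenes = 0,
                      noiseSd = 0, seed = 17)
  ds <- generateDataset(spec)
  em <- exprs(ds)
  base <- em[1, ]
  reg0 <- as.vector(regulations(edgeTransform(rbind(x = base))))
  agreeFrac <- vapply(2:6, function(g) {
    rg <- as.vector(regulations(edgeTransform(em[g, , drop = FALSE])))
    mean(rg == reg0)
  }, 0)
  # at least one member is partially inverted (window strictly inside)
  expect_true(any(agreeFrac > 0 & agreeFrac < 1))
  # the module stays densely connected through combined support; pairs with
  # non-nested windows can lose the spike edges in the window difference
  net <- buildNetwork(buildCorrelogram(edgeTransform(em)), 0.5)
  A <- adjacency(net)
  expect_gte(mean(A[upper.tri(A)] != 0), 0.75)
})
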