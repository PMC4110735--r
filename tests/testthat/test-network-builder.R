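test_that("strong connection thresholds combined support strictly", {
  expect_true(isStronglyConnected(0.6, 0.0, 0.5))
  expect_true(isStronglyConnected(0.3, 0.3, 0.5))
  expect_false(isStronglyConnected(0.5, 0.0, 0.5))
  expect_error(isStronglyConnected(0.8, 0.5, 0.5), "exceed 1")
  expect_error(isStronglyConnected(0.6, 0, theta = 1), "theta")
})

test_that("edge sign prefers the component that exceeds theta, then the larger", {
  expect_equal(edgeSign(0.8, 0.1, 0.5), 1)
  expect_equal(edgeSign(0.1, 0.8, 0.5), -1)
  expect_equal(edgeSign(0.35, 0.30, 0.5), 1)   # fallback, larger component
  expect_equal(edgeSign(0.30, 0.35, 0.5), -1)
  expect_equal(edgeSign(0.3, 0.3, 0.5), 1)     # fallback tie -> +1
  expect_error(edgeSign(0.2, 0.2, 0.5), "strongly connected")
})

test_that("identical and mirrored pairs give single signed edges", {
  set.seed(4)
  base <- 300 * exp(cumsum(rnorm(12, 0, 0.03)))
  em <- rbind(a = base, b = base + 5, c = 2 * mean(base) - base)
  net <- buildNetwork(buildCorrelogram(edgeTransform(em)), theta = 0.5)
  A <- adjacency(net)
  expect_equal(A["a", "b"], 1L)
  expect_equal(A["a", "c"], -1L)
  expect_equal(A["b", "c"], -1L)
  S <- edgeScores(net)
  expect_true(all(S[A != 0] > 0.5))
})

test_that("network equals the independent double-loop reconstruction", {
  for (seed in 1:5) {
    em <- randomExpression(100 + seed, n = 15, m = 10)
    net <- buildNetwork(buildCorrelogram(edgeTransform(em), tau = 20),
                        theta = 0.4)
    expect_identical(unname(adjacency(net)),
                     oracleAdjacency(em, tau = 20, theta = 0.4))
  }
  # and on a planted dataset
  ds <- generateDataset(patternSpec(seed = 3, genesPerModule = 4,
                                    nBackgroundGenes = 4))
  net <- buildNetwork(buildCorrelogram(edgeTransform(exprs(ds))), 0.5)
  expect_identical(unname(adjacency(net)),
                   oracleAdjacency(exprs(ds), tau = 20, theta = 0.5))
})

test_that("adjacency is symmetric with zero diagonal and {-1,0,1} entries", {
  em <- randomExpression(23, 20, 8)
  net <- buildNetwork(buildCorrelogram(edgeTransform(em)), theta = 0.3)
  A <- adjacency(net)
  expect_identical(A, t(A))
  expect_true(all(diag(A) == 0))
  expect_true(all(A %in% c(-1L, 0L, 1L)))
  # edge present iff strongly connected
  cm <- buildCorrelogram(edgeTransform(em))
  conn <- isStronglyConnected(posSupport(cm), negSupport(cm), 0.3)
  diag(conn) <- FALSE
  expect_identical(unname(A != 0), unname(conn))
})

test_that("raising theta never adds edges", {
  em <- randomExpression(29, 18, 10)
  cm <- buildCorrelogram(edgeTransform(em), tau = 40)
  prev <- NULL
  for (theta in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    A <- adjacency(buildNetwork(cm, theta))
    if (!is.null(prev)) expect_true(all(A[prev == 0] == 0))
    prev <- A
  }
})

test_that("modules are the connected components, larger first", {
  set.seed(8)
  b1 <- 300 * exp(cumsum(rnorm(10, 0, 0.03)))
  b2 <- rnorm(10, 0, 300)     # stationary, broad angle spectrum
  em <- rbind(a1 = b1, a2 = b1 + 3, a3 = b1 - 4,
              z1 = b2, z2 = b2 + 2, z3 = b2 - 2, z4 = b2 + 6,
              iso = rnorm(10, 0, 300))
  net <- buildNetwork(buildCorrelogram(edgeTransform(em)), 0.5)
  mods <- extractModules(net)
  expect_setequal(mods$gene[mods$module == 1], c("z1", "z2", "z3", "z4"))
  expect_setequal(mods$gene[mods$module == 2], c("a1", "a2", "a3"))
  expect_false("iso" %in% mods$gene)
  # each assigned gene appears exactly once: a partition
  expect_false(anyDuplicated(mods$gene) > 0)
})

test_that("mixed-sign chains form one module via sign-agnostic reachability", {
  A <- matrix(0L, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  A["a", "b"] <- A["b", "a"] <- 1L
  A["b", "c"] <- A["c", "b"] <- -1L
  S <- abs(A) * 0.8
  net <- new("SignedNetwork", geneIds = c("a", "b", "c"), adjacency = A,
             edgeScores = S, theta = 0.5)
  mods <- extractModules(net)
  expect_equal(sort(mods$gene), c("a", "b", "c"))
  expect_equal(unique(mods$module), 1L)
})

test_that("an empty network yields an empty partition", {
  em <- randomExpression(31, 5, 8)
  net <- buildNetwork(buildCorrelogram(edgeTransform(em), tau = 1), 0.9)
  mods <- extractModules(net)
  expect_equal(nrow(mods), 0L)
})

test_that("module partition on random planted data is an equivalence partition", {
  ds <- generateDataset(patternSpec(seed = 5))
  net <- buildNetwork(buildCorrelogram(edgeTransform(exprs(ds))), 0.5)
  mods <- extractModules(net)
  A <- adjacency(net) != 0
  for (m in unique(mods$module)) {
    genes <- mods$gene[mods$module == m]
    sub <- A[genes, genes, drop = FALSE]
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    expect_true(igraph::is_connected(g))
  }
  # no edges across different modules
  if (length(unique(mods$module)) > 1) {
    for (m in unique(mods$module)) {
      inside <- mods$gene[mods$module == m]
      outside <- setdiff(mods$gene, inside)
      expect_true(all(!A[inside, outside]))
    }
  }
})
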