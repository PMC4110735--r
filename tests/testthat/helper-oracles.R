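# Independent oracles: plain-arithmetic reimplementations used to
# cross-check the package's vectorised one-pass path. They deliberately
# avoid the package's similarity functions.

oracleAngle <- function(prev, nxt) {
  a <- abs(atan2(nxt, prev)) * 180 / pi
  if (nxt < prev) 180 - a else a
}

# Naive nested-loop correlogram: per pair, per edge, recompute both
# similarity rules from their definitions.
oracleCorrelogram <- function(em, tau) {
  n <- nrow(em)
  K <- ncol(em) - 1
  ang <- matrix(0, n, K)
  reg <- matrix(0, n, K)
  for (i in seq_len(n)) for (k in seq_len(K)) {
    ang[i, k] <- oracleAngle(em[i, k], em[i, k + 1])
    reg[i, k] <- if (em[i, k + 1] < em[i, k]) -1 else 1
  }
  pos <- matrix(0L, n, n)
  neg <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    for (k in seq_len(K)) {
      if (reg[i, k] == reg[j, k] && abs(ang[i, k] - ang[j, k]) < tau)
        pos[i, j] <- pos[i, j] + 1L
      if (reg[i, k] == -reg[j, k] &&
          abs(180 - (ang[i, k] + ang[j, k])) < tau)
        neg[i, j] <- neg[i, j] + 1L
    }
    pos[j, i] <- pos[i, j]
    neg[j, i] <- neg[i, j]
  }
  list(pos = pos, neg = neg, K = K)
}

oracleAdjacency <- function(em, tau, theta) {
  oc <- oracleCorrelogram(em, tau)
  n <- nrow(em)
  A <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ps <- oc$pos[i, j] / oc$K
    ns <- oc$neg[i, j] / oc$K
    if (ps + ns > theta) {
      A[i, j] <- if (ps > theta) 1L
        else if (ns > theta) -1L
        else if (ps >= ns) 1L else -1L
      A[j, i] <- A[i, j]
    }
  }
  A
}

randomExpression <- function(seed, n, m) {
  set.seed(seed)
  matrix(rnorm(n * m, 0, 100), n, m,
         dimnames = list(sprintf("g%02d", seq_len(n)), NULL))
}

# Planted-recovery summary used by synthetic-data and acceptance tests.
recoveryStats <- function(seed, noiseSd = 10, nBackgroundGenes = 10,
                          tau = 20, theta = 0.5) {
  ds <- generateDataset(patternSpec(seed = seed, noiseSd = noiseSd,
                                    nBackgroundGenes = nBackgroundGenes))
  net <- buildNetwork(buildCorrelogram(edgeTransform(exprs(ds)), tau = tau),
                      theta = theta)
  A <- adjacency(net)
  lab <- moduleLabels(ds)
  truth <- outer(lab, lab, function(x, y) x == y & x > 0)
  diag(truth) <- FALSE
  ut <- upper.tri(A)
  tp <- sum(A[ut] != 0 & truth[ut])
  fp <- sum(A[ut] != 0 & !truth[ut])
  fn <- sum(A[ut] == 0 & truth[ut])
  ts <- outer(orientations(ds), orientations(ds))
  rec <- (A != 0) & truth
  c(precision = if (tp + fp == 0) 1 else tp / (tp + fp),
    recall = tp / (tp + fn),
    signAgreement = if (any(rec)) mean(A[rec] == ts[rec]) else NA_real_)
}
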