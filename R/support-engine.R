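#' Positive pattern similarity of two edges
#'
#' Two genes' k-th edges are positively similar when they step in the same
#' direction and their degrees of fluctuation differ by less than the angle
#' threshold tau (strict inequality).
#'
#' @param angleI,angleJ angles in degrees, each in \[0, 180\] (vectorised).
#' @param regI,regJ regulation signs in \{-1, +1\} (vectorised).
#' @param tau angle threshold in degrees, 0 < tau < 180. The default 20 sits
#'   in the middle of the 15-25 range that works well in practice.
#' @return integer vector of 0/1 match indicators.
#' @examples
#' posSim(52, 1, 52, 1, 20)    # 1
#' posSim(52, 1, 138, -1, 20)  # 0, regulation mismatch
#' posSim(30, 1, 55, 1, 20)    # 0, |30 - 55| >= 20
#' @seealso [negSim()], [buildCorrelogram()]
#' @export
posSim <- function(angleI, regI, angleJ, regJ, tau = 20) {
  .checkSimArgs(angleI, regI, angleJ, regJ, tau)
  as.integer(regI == regJ & abs(angleI - angleJ) < tau)
}

#' Negative pattern similarity of two edges
#'
#' Two genes' k-th edges are negatively similar when they step in opposite
#' directions and the sum of their degrees of fluctuation is within tau of
#' 180 degrees (strict inequality): a perfect mirror pair (a, 180 - a)
#' deviates by zero.
#'
#' @inheritParams posSim
#' @return integer vector of 0/1 match indicators.
#' @examples
#' negSim(138, -1, 52, 1, 20)   # 1, |180 - (138 + 52)| = 10
#' negSim(138, -1, 138, -1, 20) # 0, same regulation
#' negSim(90, 1, 90, -1, 1)     # 1, perfect mirror
#' @seealso [posSim()], [buildCorrelogram()]
#' @export
negSim <- function(angleI, regI, angleJ, regJ, tau = 20) {
  .checkSimArgs(angleI, regI, angleJ, regJ, tau)
  as.integer(regI == -regJ & abs(180 - (angleI + angleJ)) < tau)
}

.checkSimArgs <- function(angleI, regI, angleJ, regJ, tau) {
  if (length(tau) != 1L || !is.finite(tau) || tau <= 0 || tau >= 180)
    stop("tau must be a single value in (0, 180)")
  if (any(angleI < 0 | angleI > 180) || any(angleJ < 0 | angleJ > 180))
    stop("angles must lie in [0, 180]")
  if (!all(regI %in% c(-1, 1)) || !all(regJ %in% c(-1, 1)))
    stop("regulation signs must be -1 or +1")
  invisible(TRUE)
}

#' Accumulate the pair-wise correlogram in one pass over the edge table
#'
#' Scans the transposed edge representation once: for each of the M-1 edge
#' columns, all N(N-1)/2 unordered gene pairs are compared at that edge and
#' the positive/negative match counters of the triangular correlogram are
#' incremented. After the single scan the correlogram holds, for every pair,
#' the number of edges at which the two profiles matched positively and
#' negatively; supports are read from it without revisiting the data.
#'
#' @param er an [EdgeRepresentation-class].
#' @param tau angle threshold in degrees (see [posSim()]).
#' @return a [Correlogram-class].
#' @examples
#' em <- rbind(G1 = c(1, 5, 2, 8), G2 = c(2, 6, 3, 9))
#' cm <- buildCorrelogram(edgeTransform(em), tau = 20)
#' posCounts(cm)["G1", "G2"]  # 3: identical patterns at all 3 edges
#' @seealso [posSupport()], [negSupport()], [buildNetwork()]
#' @export
buildCorrelogram <- function(er, tau = 20) {
  stopifnot(methods::is(er, "EdgeRepresentation"))
  n <- length(er@geneIds)
  if (n < 2L) stop("buildCorrelogram: need at least 2 genes")
  K <- ncol(er@angles)
  ut <- upper.tri(matrix(0L, n, n))
  idx <- which(ut, arr.ind = TRUE)
  ord <- .pairIndex(idx[, 1], idx[, 2], n)
  pos <- integer(n * (n - 1L) / 2L)
  neg <- integer(n * (n - 1L) / 2L)
  for (k in seq_len(K)) {  # the single pass: each edge column visited once
    a <- er@angles[, k]
    r <- er@regulations[, k]
    pm <- (outer(r, r, "==") & abs(outer(a, a, "-")) < tau)[ut]
    nm <- (outer(r, r, function(x, y) x == -y) &
             abs(180 - outer(a, a, "+")) < tau)[ut]
    pos[ord] <- pos[ord] + as.integer(pm)
    neg[ord] <- neg[ord] + as.integer(nm)
  }
  methods::new("Correlogram", geneIds = er@geneIds, posCounts = pos,
               negCounts = neg, nEdges = as.integer(K), tau = tau)
}

#' Positive and negative support of a gene pair
#'
#' The support of a pair is the fraction of its M-1 edges at which the two
#' profiles match, counted separately for positive (same-direction) and
#' negative (mirrored) matching. Both supports lie in \[0, 1\] and their sum
#' cannot exceed 1 because a single edge pair cannot match both ways.
#'
#' @param cm a [Correlogram-class].
#' @param i,j gene identifiers or indices of a pair (i != j). When omitted,
#'   the full symmetric support matrix is returned.
#' @return a support fraction, or the symmetric N x N support matrix.
#' @examples
#' em <- rbind(G1 = c(1, 5, 2, 8), G2 = c(2, 6, 3, 9))
#' cm <- buildCorrelogram(edgeTransform(em))
#' posSupport(cm, "G1", "G2")  # 1
#' negSupport(cm, "G1", "G2")  # 0
#' @export
posSupport <- function(cm, i = NULL, j = NULL) {
  .support(cm, i, j, cm@posCounts)
}

#' @rdname posSupport
#' @export
negSupport <- function(cm, i = NULL, j = NULL) {
  .support(cm, i, j, cm@negCounts)
}

.support <- function(cm, i, j, counts) {
  stopifnot(methods::is(cm, "Correlogram"))
  if (is.null(i) != is.null(j))
    stop("supply both i and j, or neither")
  if (is.null(i))
    return(.pairVecToMatrix(counts, cm@geneIds) / cm@nEdges)
  i <- .resolveGene(cm@geneIds, i)
  j <- .resolveGene(cm@geneIds, j)
  if (i == j) stop("support is undefined for a self-pair")
  counts[.pairIndex(i, j, length(cm@geneIds))] / cm@nEdges
}

.resolveGene <- function(ids, g) {
  if (is.character(g)) {
    pos <- match(g, ids)
    if (anyNA(pos)) stop("unknown gene identifier: ", g)
    pos
  } else {
    g <- as.integer(g)
    if (g < 1L || g > length(ids)) stop("gene index out of range: ", g)
    g
  }
}
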