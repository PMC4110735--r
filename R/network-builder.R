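#' Strong-connection test for a gene pair
#'
#' A pair is strongly connected when its combined positive + negative
#' support strictly exceeds the threshold theta. Keeping theta at or above
#' 0.5 requires the profiles to match at a majority of their edges.
#'
#' @param pos,neg support fractions in \[0, 1\] with pos + neg <= 1
#'   (vectorised).
#' @param theta support threshold, 0 <= theta < 1; default 0.5.
#' @return logical vector.
#' @examples
#' isStronglyConnected(0.6, 0.0, 0.5)  # TRUE
#' isStronglyConnected(0.3, 0.3, 0.5)  # TRUE, 0.6 > 0.5
#' isStronglyConnected(0.5, 0.0, 0.5)  # FALSE, strict inequality
#' @seealso [edgeSign()], [buildNetwork()]
#' @export
isStronglyConnected <- function(pos, neg, theta = 0.5) {
  .checkSupportArgs(pos, neg, theta)
  pos + neg > theta
}

#' Sign of a strongly connected edge
#'
#' +1 when the positive support alone exceeds theta, -1 when the negative
#' support alone does. When the pair is connected only through the combined
#' support (possible when theta < 0.5), the larger component decides, ties
#' going to +1; with theta >= 0.5 at most one component can exceed theta,
#' so the fallback never fires there.
#'
#' @inheritParams isStronglyConnected
#' @return numeric vector with entries in \{-1, +1\}.
#' @examples
#' edgeSign(0.8, 0.1, 0.5)    # +1
#' edgeSign(0.1, 0.8, 0.5)    # -1
#' edgeSign(0.35, 0.30, 0.5)  # +1, fallback to the larger component
#' @export
edgeSign <- function(pos, neg, theta = 0.5) {
  .checkSupportArgs(pos, neg, theta)
  if (!all(isStronglyConnected(pos, neg, theta)))
    stop("edgeSign is defined only for strongly connected pairs")
  ifelse(pos > theta, 1, ifelse(neg > theta, -1, ifelse(pos >= neg, 1, -1)))
}

.checkSupportArgs <- function(pos, neg, theta) {
  if (length(theta) != 1L || !is.finite(theta) || theta < 0 || theta >= 1)
    stop("theta must be a single value in [0, 1)")
  if (any(pos < 0 | pos > 1) || any(neg < 0 | neg > 1))
    stop("supports must lie in [0, 1]")
  if (any(pos + neg > 1 + 1e-12))
    stop("pos + neg support cannot exceed 1")
  invisible(TRUE)
}

#' Build the signed co-expression network from a correlogram
#'
#' Thresholds the pair supports stored in the correlogram into a symmetric
#' signed adjacency matrix: every strongly connected pair becomes an edge
#' whose sign encodes positive (+1) or negative (-1) co-regulation and whose
#' score is the combined support. Each unordered pair is examined exactly
#' once, reading counts from the triangular correlogram; the expression data
#' are not revisited.
#'
#' @param cm a [Correlogram-class].
#' @param theta support threshold (see [isStronglyConnected()]).
#' @return a [SignedNetwork-class].
#' @examples
#' em <- rbind(G1 = c(1, 5, 2, 8), G2 = c(2, 6, 3, 9), G3 = c(9, 1, 7, 0))
#' net <- buildNetwork(buildCorrelogram(edgeTransform(em)), theta = 0.5)
#' adjacency(net)
#' @seealso [extractModules()], [writeSignedEdgelist()]
#' @export
buildNetwork <- function(cm, theta = 0.5) {
  stopifnot(methods::is(cm, "Correlogram"))
  if (length(theta) != 1L || !is.finite(theta) || theta < 0 || theta >= 1)
    stop("theta must be a single value in [0, 1)")
  n <- length(cm@geneIds)
  pos <- cm@posCounts / cm@nEdges
  neg <- cm@negCounts / cm@nEdges
  conn <- pos + neg > theta
  sgn <- integer(length(conn))
  if (any(conn))
    sgn[conn] <- as.integer(edgeSign(pos[conn], neg[conn], theta))
  score <- ifelse(conn, pos + neg, 0)
  A <- .pairVecToMatrix(sgn, cm@geneIds)
  S <- .pairVecToMatrix(score, cm@geneIds)
  storage.mode(A) <- "integer"
  methods::new("SignedNetwork", geneIds = cm@geneIds, adjacency = A,
               edgeScores = S, theta = theta)
}

#' Extract co-expression modules as connected components
#'
#' Genes reachable from one another through network edges (of either sign)
#' form a module; a gene belongs to at most one module and isolated genes
#' belong to none. Modules smaller than `minSize` are dropped. Module
#' identifiers are assigned by decreasing module size, ties broken by the
#' lexicographically smallest member.
#'
#' @param net a [SignedNetwork-class].
#' @param minSize smallest module size reported; default 2 (a single gene is
#'   not a co-expression module).
#' @return data.frame with columns `gene` and `module` (integer identifier),
#'   one row per assigned gene, ordered by module then gene.
#' @examples
#' em <- rbind(G1 = c(1, 5, 2, 8), G2 = c(2, 6, 3, 9), G3 = c(9, 1, 7, 0))
#' extractModules(buildNetwork(buildCorrelogram(edgeTransform(em))))
#' @export
extractModules <- function(net, minSize = 2) {
  stopifnot(methods::is(net, "SignedNetwork"))
  A <- abs(net@adjacency)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  keep <- which(comp$csize >= max(2, minSize))
  if (!length(keep))
    return(data.frame(gene = character(0), module = integer(0)))
  members <- lapply(keep, function(cc) sort(net@geneIds[comp$membership == cc]))
  ord <- order(-lengths(members), vapply(members, `[`, "", 1L))
  members <- members[ord]
  data.frame(
    gene = unlist(members, use.names = FALSE),
    module = rep.int(seq_along(members), lengths(members)))
}
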