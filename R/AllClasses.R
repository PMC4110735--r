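#' @import methods
NULL

#' EdgeRepresentation: per-edge angular deviation and regulation sign
#'
#' The edge representation of an expression matrix. A profile of M conditions
#' has M-1 "edges" (segments between consecutive expression values). Each edge
#' is summarised by its degree of fluctuation (an angle in degrees on the
#' 180-degree plane, computed with the two-argument arctangent of the two
#' bounding values) and its regulation sign (+1 for an upward step, -1 for a
#' downward step).
#'
#' @slot geneIds character vector of unique gene identifiers.
#' @slot angles numeric N x (M-1) matrix of angles in degrees, each in
#'   \[0, 180\]; stored at full precision (the degree-rounded values some
#'   worked examples print are for display only).
#' @slot regulations numeric N x (M-1) matrix with entries in \{-1, +1\}.
#'
#' @seealso [edgeTransform()]
#' @export
setClass("EdgeRepresentation",
  representation(geneIds = "character", angles = "matrix",
                 regulations = "matrix"))

setValidity("EdgeRepresentation", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@geneIds))
    msg <- c(msg, "gene identifiers must be unique")
  if (nrow(object@angles) != length(object@geneIds))
    msg <- c(msg, "angles row count must match geneIds")
  if (!identical(dim(object@angles), dim(object@regulations)))
    msg <- c(msg, "angles and regulations must have identical dimensions")
  if (length(object@angles)) {
    if (anyNA(object@angles) || any(!is.finite(object@angles)))
      msg <- c(msg, "angles must be finite")
    else if (any(object@angles < 0 | object@angles > 180))
      msg <- c(msg, "angles must lie in [0, 180]")
    if (!all(object@regulations %in% c(-1, 1)))
      msg <- c(msg, "regulations must be -1 or +1")
  }
  if (length(msg)) msg else TRUE
})

#' Correlogram: triangular pair-count structure of matching edges
#'
#' For every unordered gene pair, the number of edges at which the two
#' profiles are positively similar (same regulation, close angles) and
#' negatively similar (opposite regulation, angle sum close to 180 degrees),
#' accumulated in a single pass over the transposed edge table. Counts are
#' stored as upper-triangular vectors of length N(N-1)/2, matching the
#' fixed-memory contract of the one-pass construction.
#'
#' @slot geneIds character vector of gene identifiers.
#' @slot posCounts integer vector, upper-triangular by row
#'   (pairs (1,2), (1,3), ..., (N-1,N)).
#' @slot negCounts integer vector, same layout.
#' @slot nEdges integer, the number of edges M-1 the counts were taken over.
#' @slot tau numeric, the angle threshold (degrees) used for similarity.
#'
#' @seealso [buildCorrelogram()], [posSupport()], [negSupport()]
#' @export
setClass("Correlogram",
  representation(geneIds = "character", posCounts = "integer",
                 negCounts = "integer", nEdges = "integer", tau = "numeric"))

setValidity("Correlogram", function(object) {
  n <- length(object@geneIds)
  np <- n * (n - 1L) / 2L
  msg <- character(0)
  if (length(object@posCounts) != np || length(object@negCounts) != np)
    msg <- c(msg, "count vectors must have length N(N-1)/2")
  if (length(object@posCounts)) {
    if (any(object@posCounts < 0L) || any(object@negCounts < 0L))
      msg <- c(msg, "counts must be non-negative")
    if (any(object@posCounts + object@negCounts > object@nEdges))
      msg <- c(msg, "pos + neg counts cannot exceed the number of edges")
  }
  if (length(msg)) msg else TRUE
})

#' SignedNetwork: signed co-expression adjacency with support scores
#'
#' Symmetric adjacency over genes with entries in \{-1, 0, +1\}: +1 marks a
#' positively co-regulated pair, -1 a negatively co-regulated pair, 0 no
#' relation. Each nonzero pair also carries its combined support
#' (positive + negative support fraction), the score that exceeded the
#' connection threshold theta.
#'
#' @slot geneIds character vector of gene identifiers.
#' @slot adjacency integer N x N matrix, symmetric, zero diagonal,
#'   entries in \{-1, 0, +1\}.
#' @slot edgeScores numeric N x N matrix of combined supports, nonzero
#'   exactly where adjacency is nonzero.
#' @slot theta numeric, the support threshold used.
#'
#' @seealso [buildNetwork()], [extractModules()]
#' @export
setClass("SignedNetwork",
  representation(geneIds = "character", adjacency = "matrix",
                 edgeScores = "matrix", theta = "numeric"))

setValidity("SignedNetwork", function(object) {
  A <- object@adjacency
  msg <- character(0)
  if (nrow(A) != length(object@geneIds) || ncol(A) != length(object@geneIds))
    msg <- c(msg, "adjacency must be N x N")
  else {
    if (!all(A %in% c(-1, 0, 1))) msg <- c(msg, "adjacency entries must be -1, 0 or +1")
    if (!isTRUE(all.equal(A, t(A)))) msg <- c(msg, "adjacency must be symmetric")
    if (any(diag(A) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
    if (!identical(dim(A), dim(object@edgeScores)))
      msg <- c(msg, "edgeScores must match adjacency dimensions")
    else if (any((object@edgeScores != 0) != (A != 0)))
      msg <- c(msg, "edgeScores must be nonzero exactly at network edges")
  }
  if (length(msg)) msg else TRUE
})

#' GoldStandard: reference set of positive gene pairs
#'
#' An undirected gold-standard network: a universe of gene identifiers and a
#' set of unordered pairs labelled positive; every other pair of the universe
#' is implicitly negative. Directed edge lists (the DREAM dialect) are
#' symmetrised on reading: a pair is positive if either direction is.
#'
#' @slot geneIds character vector, the gene universe.
#' @slot pairs character matrix with two columns; each row one positive
#'   unordered pair, stored with the lexicographically smaller gene first.
#'
#' @seealso [readGoldEdgelist()], [evaluateNetwork()]
#' @export
setClass("GoldStandard",
  representation(geneIds = "character", pairs = "matrix"))

setValidity("GoldStandard", function(object) {
  msg <- character(0)
  p <- object@pairs
  if (ncol(p) != 2 && nrow(p) > 0) msg <- c(msg, "pairs must have two columns")
  if (nrow(p)) {
    if (any(p[, 1] == p[, 2])) msg <- c(msg, "self-pairs are not allowed")
    if (!all(p %in% object@geneIds))
      msg <- c(msg, "all pair members must belong to the gene universe")
    if (anyDuplicated(paste(p[, 1], p[, 2])))
      msg <- c(msg, "duplicate pairs are not allowed")
    if (any(p[, 1] >= p[, 2]))
      msg <- c(msg, "pairs must be stored smaller-id first")
  }
  if (length(msg)) msg else TRUE
})

#' PatternSpec: parameters of the synthetic pattern generator
#'
#' Describes a synthetic expression dataset with planted co-regulation
#' modules. Each module is grown from an independent base profile; members
#' are derived as shifted (additive offset), scaled (multiplicative factor),
#' inverted (reflection about the base mean) or mixed (reflection on a
#' contiguous window) transforms of the base, plus additive Gaussian noise.
#' Background genes are independent profiles with no planted structure.
#'
#' @slot nModules integer, number of planted modules.
#' @slot genesPerModule integer (>= 2).
#' @slot nConditions integer (>= 3).
#' @slot patternKinds character, one of "shifted", "scaled", "inverted",
#'   "mixed" per module (recycled to nModules).
#' @slot alpha numeric, magnitude of additive offsets (expression units);
#'   member offsets are drawn uniformly from \[-alpha, alpha\].
#' @slot betaScale numeric > 1, scale factor bound; member factors are drawn
#'   log-uniformly from \[1/betaScale, betaScale\].
#' @slot noiseSd numeric >= 0, additive Gaussian noise sd (expression units).
#' @slot nBackgroundGenes integer >= 0.
#' @slot seed integer, master seed; all randomness derives from it.
#'
#' @seealso [patternSpec()], [generateDataset()]
#' @export
setClass("PatternSpec",
  representation(nModules = "integer", genesPerModule = "integer",
                 nConditions = "integer", patternKinds = "character",
                 alpha = "numeric", betaScale = "numeric", noiseSd = "numeric",
                 nBackgroundGenes = "integer", seed = "integer"))

setValidity("PatternSpec", function(object) {
  msg <- character(0)
  if (object@genesPerModule < 2L) msg <- c(msg, "genesPerModule must be >= 2")
  if (object@nConditions < 3L) msg <- c(msg, "nConditions must be >= 3")
  if (object@betaScale <= 0) msg <- c(msg, "betaScale must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@nBackgroundGenes < 0L) msg <- c(msg, "nBackgroundGenes must be >= 0")
  kinds <- c("shifted", "scaled", "inverted", "mixed")
  if (!all(object@patternKinds %in% kinds))
    msg <- c(msg, sprintf("patternKinds must be among: %s",
                          paste(kinds, collapse = ", ")))
  if (length(object@patternKinds) != object@nModules)
    msg <- c(msg, "patternKinds must have one entry per module")
  if (length(msg)) msg else TRUE
})

#' SyntheticDataset: expression matrix with planted ground truth
#'
#' @slot exprs numeric gene x condition matrix with gene identifiers as row
#'   names and condition identifiers as column names.
#' @slot gold [GoldStandard-class] with every within-module pair positive.
#' @slot moduleLabels integer vector named by gene; 0 marks background genes.
#' @slot orientations numeric vector named by gene: +1 for members that
#'   follow their module base (shifted/scaled/direct), -1 for reflected
#'   (inverted) members; the truth sign of a pair is the product of its
#'   members' orientations.
#' @slot spec the [PatternSpec-class] that produced the dataset.
#'
#' @seealso [generateDataset()]
#' @export
setClass("SyntheticDataset",
  representation(exprs = "matrix", gold = "GoldStandard",
                 moduleLabels = "integer", orientations = "numeric",
                 spec = "PatternSpec"))

#' EvalScores: network prediction scores against a gold standard
#'
#' @slot aupr numeric, area under the precision-vs-recall curve.
#' @slot auroc numeric, area under the ROC curve.
#' @slot fBetaMax numeric, maximum F-beta over the threshold sweep.
#' @slot fBetaAvg numeric, mean F-beta over the threshold sweep.
#' @slot beta numeric, the F-score weight used.
#' @slot prPoints data.frame with columns recall, precision.
#' @slot rocPoints data.frame with columns fpr, tpr.
#'
#' @seealso [evaluateNetwork()]
#' @export
setClass("EvalScores",
  representation(aupr = "numeric", auroc = "numeric", fBetaMax = "numeric",
                 fBetaAvg = "numeric", beta = "numeric",
                 prPoints = "data.frame", rocPoints = "data.frame"))
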