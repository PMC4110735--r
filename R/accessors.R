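#' @describeIn EdgeRepresentation gene identifiers.
#' @param object an object of the documented class.
#' @export
setMethod("geneIds", "EdgeRepresentation", function(object) object@geneIds)

#' @describeIn EdgeRepresentation angle matrix (degrees).
#' @export
setMethod("angles", "EdgeRepresentation", function(object) object@angles)

#' @describeIn EdgeRepresentation regulation-sign matrix.
#' @export
setMethod("regulations", "EdgeRepresentation", function(object) object@regulations)

#' @describeIn EdgeRepresentation number of edges (M - 1).
#' @export
setMethod("nEdges", "EdgeRepresentation", function(object) ncol(object@angles))

#' @describeIn Correlogram gene identifiers.
#' @param object an object of the documented class.
#' @export
setMethod("geneIds", "Correlogram", function(object) object@geneIds)

#' @describeIn Correlogram number of edges the counts were accumulated over.
#' @export
setMethod("nEdges", "Correlogram", function(object) object@nEdges)

#' @describeIn Correlogram symmetric matrix of positive match counts.
#' @export
setMethod("posCounts", "Correlogram", function(object)
  .pairVecToMatrix(object@posCounts, object@geneIds))

#' @describeIn Correlogram symmetric matrix of negative match counts.
#' @export
setMethod("negCounts", "Correlogram", function(object)
  .pairVecToMatrix(object@negCounts, object@geneIds))

#' @describeIn SignedNetwork gene identifiers.
#' @param object an object of the documented class.
#' @export
setMethod("geneIds", "SignedNetwork", function(object) object@geneIds)

#' @describeIn SignedNetwork signed adjacency matrix.
#' @export
setMethod("adjacency", "SignedNetwork", function(object) object@adjacency)

#' @describeIn SignedNetwork combined-support score matrix.
#' @export
setMethod("edgeScores", "SignedNetwork", function(object) object@edgeScores)

#' @describeIn GoldStandard gene universe.
#' @param object an object of the documented class.
#' @export
setMethod("geneIds", "GoldStandard", function(object) object@geneIds)

#' @describeIn GoldStandard positive unordered pairs.
#' @export
setMethod("positivePairs", "GoldStandard", function(object) object@pairs)

#' @describeIn SyntheticDataset gene identifiers.
#' @param object an object of the documented class.
#' @export
setMethod("geneIds", "SyntheticDataset", function(object) rownames(object@exprs))

#' @describeIn SyntheticDataset expression matrix.
#' @export
setMethod("exprs", "SyntheticDataset", function(object) object@exprs)

#' @describeIn SyntheticDataset ground-truth network.
#' @export
setMethod("goldStandard", "SyntheticDataset", function(object) object@gold)

#' @describeIn SyntheticDataset planted module labels (0 = background).
#' @export
setMethod("moduleLabels", "SyntheticDataset", function(object) object@moduleLabels)

#' @describeIn SyntheticDataset member orientations (+1 direct, -1 reflected).
#' @export
setMethod("orientations", "SyntheticDataset", function(object) object@orientations)

setMethod("show", "EdgeRepresentation", function(object) {
  cat(sprintf("EdgeRepresentation: %d genes, %d edges (angles in degrees)\n",
              length(object@geneIds), ncol(object@angles)))
})

setMethod("show", "Correlogram", function(object) {
  cat(sprintf(
    "Correlogram: %d genes, %d pairs, %d edges, tau = %g degrees\n",
    length(object@geneIds), length(object@posCounts), object@nEdges,
    object@tau))
})

setMethod("show", "SignedNetwork", function(object) {
  A <- object@adjacency
  up <- A[upper.tri(A)]
  cat(sprintf(
    "SignedNetwork: %d genes, %d edges (%d positive, %d negative), theta = %g\n",
    length(object@geneIds), sum(up != 0), sum(up == 1), sum(up == -1),
    object@theta))
})

setMethod("show", "GoldStandard", function(object) {
  cat(sprintf("GoldStandard: %d genes, %d positive pairs\n",
              length(object@geneIds), nrow(object@pairs)))
})

setMethod("show", "PatternSpec", function(object) {
  cat(sprintf(
    "PatternSpec: %d modules (%s) x %d genes, %d conditions, %d background\n",
    object@nModules, paste(object@patternKinds, collapse = "/"),
    object@genesPerModule, object@nConditions, object@nBackgroundGenes))
  cat(sprintf("  alpha = %g, betaScale = %g, noiseSd = %g, seed = %d\n",
              object@alpha, object@betaScale, object@noiseSd, object@seed))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf(
    "SyntheticDataset: %d genes x %d conditions, %d truth pairs\n",
    nrow(object@exprs), ncol(object@exprs), nrow(object@gold@pairs)))
})

setMethod("show", "EvalScores", function(object) {
  cat(sprintf(
    "EvalScores: AUPR = %.4f, AUROC = %.4f, max F%.1f = %.4f (avg %.4f)\n",
    object@aupr, object@auroc, object@beta, object@fBetaMax, object@fBetaAvg))
})
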