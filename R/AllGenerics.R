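#' Gene identifiers of an object
#' @param object an object carrying gene identifiers.
#' @return character vector.
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' Angle matrix of an edge representation
#' @param object an [EdgeRepresentation-class].
#' @return numeric N x (M-1) matrix of degrees in \[0, 180\].
#' @export
setGeneric("angles", function(object) standardGeneric("angles"))

#' Regulation-sign matrix of an edge representation
#' @param object an [EdgeRepresentation-class].
#' @return numeric N x (M-1) matrix with entries in \{-1, +1\}.
#' @export
setGeneric("regulations", function(object) standardGeneric("regulations"))

#' Number of profile edges (M - 1)
#' @param object an [EdgeRepresentation-class] or [Correlogram-class].
#' @return integer.
#' @export
setGeneric("nEdges", function(object) standardGeneric("nEdges"))

#' Positive match counts of a correlogram
#' @param object a [Correlogram-class].
#' @return symmetric integer matrix of per-pair positive match counts.
#' @export
setGeneric("posCounts", function(object) standardGeneric("posCounts"))

#' Negative match counts of a correlogram
#' @param object a [Correlogram-class].
#' @return symmetric integer matrix of per-pair negative match counts.
#' @export
setGeneric("negCounts", function(object) standardGeneric("negCounts"))

#' Signed adjacency matrix of a network
#' @param object a [SignedNetwork-class].
#' @return integer matrix with entries in \{-1, 0, +1\}.
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))

#' Combined-support scores of network edges
#' @param object a [SignedNetwork-class].
#' @return numeric matrix, nonzero at network edges.
#' @export
setGeneric("edgeScores", function(object) standardGeneric("edgeScores"))

#' Positive pairs of a gold standard
#' @param object a [GoldStandard-class].
#' @return two-column character matrix of unordered positive pairs.
#' @export
setGeneric("positivePairs", function(object) standardGeneric("positivePairs"))

#' Expression matrix of a synthetic dataset
#' @param object a [SyntheticDataset-class].
#' @return numeric gene x condition matrix.
#' @export
setGeneric("exprs", function(object) standardGeneric("exprs"))

#' Ground-truth network of a synthetic dataset
#' @param object a [SyntheticDataset-class].
#' @return a [GoldStandard-class].
#' @export
setGeneric("goldStandard", function(object) standardGeneric("goldStandard"))

#' Planted module labels of a synthetic dataset
#' @param object a [SyntheticDataset-class].
#' @return integer vector named by gene; 0 for background genes.
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))

#' Member orientations of a synthetic dataset
#'
#' +1 for members following their module base, -1 for reflected (inverted)
#' members. The ground-truth sign of a within-module pair is the product of
#' the two members' orientations.
#' @param object a [SyntheticDataset-class].
#' @return numeric vector named by gene.
#' @export
setGeneric("orientations", function(object) standardGeneric("orientations"))
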