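#' Reconstruct a signed co-expression network from an expression matrix
#'
#' Convenience wrapper running the full reconstruction: edge transform,
#' one-pass correlogram, support thresholding and module extraction.
#'
#' @param x numeric gene x condition matrix (or SummarizedExperiment).
#' @param tau angle threshold in degrees; default 20 (useful range 15-25).
#' @param theta support threshold; default 0.5 (a majority of edges must
#'   match).
#' @param minModuleSize smallest reported module; default 2.
#' @return list with components `edges` ([EdgeRepresentation-class]),
#'   `correlogram` ([Correlogram-class]), `network` ([SignedNetwork-class])
#'   and `modules` (data.frame).
#' @examples
#' sd <- generateDataset(patternSpec(seed = 1))
#' res <- geconNetwork(exprs(sd))
#' res$network
#' @export
geconNetwork <- function(x, tau = 20, theta = 0.5, minModuleSize = 2) {
  er <- edgeTransform(x)
  cm <- buildCorrelogram(er, tau = tau)
  net <- buildNetwork(cm, theta = theta)
  list(edges = er, correlogram = cm, network = net,
       modules = extractModules(net, minSize = minModuleSize))
}
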