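# Internal helpers for the triangular pair storage used by Correlogram.
# Pairs are laid out row-wise over the upper triangle:
# (1,2), (1,3), ..., (1,N), (2,3), ..., (N-1,N).

.pairIndex <- function(i, j, n) {
  if (any(i == j)) stop("self-pairs have no index in the triangular storage")
  lo <- pmin(i, j); hi <- pmax(i, j)
  (lo - 1) * n - lo * (lo - 1) / 2 + (hi - lo)
}

.pairVecToMatrix <- function(v, ids) {
  n <- length(ids)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  ut <- which(upper.tri(m), arr.ind = TRUE)
  m[ut] <- v[.pairIndex(ut[, 1], ut[, 2], n)]
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

.asExpressionMatrix <- function(x) {
  if (!is.matrix(x) && methods::is(x, "SummarizedExperiment")) {
    if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
      stop("the SummarizedExperiment package is required for this input type")
    x <- SummarizedExperiment::assay(x)
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression input must be a numeric matrix (genes x conditions)")
  if (is.null(rownames(x)))
    rownames(x) <- paste0("G", seq_len(nrow(x)))
  if (is.null(colnames(x)))
    colnames(x) <- paste0("T", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression matrix contains missing or non-finite values")
  if (nrow(x) < 1L || ncol(x) < 2L)
    stop("expression matrix needs at least 1 gene and 2 conditions")
  x
}

# Canonical unordered-pair keys, smaller id first.
.pairKeys <- function(a, b) {
  lo <- ifelse(a < b, a, b)
  hi <- ifelse(a < b, b, a)
  paste(lo, hi, sep = "\r")
}
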