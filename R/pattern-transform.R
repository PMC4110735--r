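#' Regulation sign of a profile edge
#'
#' The regulation pattern of the edge between two consecutive expression
#' values: +1 for an upward step (prev < next), -1 for a downward step.
#' Equal values are assigned +1; ties are measure-zero in continuous
#' expression data and a deterministic convention keeps the two-letter
#' alphabet intact.
#'
#' @param prev,next_ finite numeric vectors (recycled) of the earlier and
#'   later expression value bounding the edge.
#' @return numeric vector with entries in \{-1, +1\}.
#' @examples
#' regulationSign(343, 314)  # -1, downward
#' regulationSign(314, 409)  # +1, upward
#' @seealso [fluctuationAngle()], [edgeTransform()]
#' @export
regulationSign <- function(prev, next_) {
  if (anyNA(prev) || anyNA(next_) || any(!is.finite(prev)) || any(!is.finite(next_)))
    stop("regulationSign: inputs must be finite")
  ifelse(next_ < prev, -1, 1)
}

#' Degree of fluctuation of a profile edge
#'
#' The angular deviation of the edge on the 180-degree plane, from the
#' two-argument arctangent of the later value against the earlier one:
#' 180 - |atan2(next, prev)| when the step is downward, |atan2(next, prev)|
#' otherwise, in degrees. The two-argument form keeps quadrant information
#' when expression values are negative (log-ratio data). The result always
#' lies in \[0, 180\].
#'
#' The argument order -- later value first -- is deliberate and matches the
#' published form of the transform; the worked example profile
#' \{343, 314, 409\} maps to angles 137.53 and 52.49 degrees, printed as
#' \{138, 52\} after rounding.
#'
#' A (0, 0) edge is degenerate; atan2 returns 0 and the angle is reported
#' as 0 with a warning.
#'
#' @inheritParams regulationSign
#' @return numeric vector of angles in degrees, each in \[0, 180\].
#' @examples
#' round(fluctuationAngle(343, 314))  # 138
#' round(fluctuationAngle(314, 409))  # 52
#' fluctuationAngle(1, 1)             # 45
#' @seealso [regulationSign()], [edgeTransform()]
#' @export
fluctuationAngle <- function(prev, next_) {
  if (anyNA(prev) || anyNA(next_) || any(!is.finite(prev)) || any(!is.finite(next_)))
    stop("fluctuationAngle: inputs must be finite")
  if (any(prev == 0 & next_ == 0))
    warning("degenerate (0, 0) edge; angle reported as 0")
  a <- abs(atan2(next_, prev)) * 180 / pi
  ifelse(next_ < prev, 180 - a, a)
}

#' Transform an expression matrix into its edge representation
#'
#' Converts an N x M expression matrix into N x (M-1) matrices of degrees of
#' fluctuation and regulation signs, one column per edge between consecutive
#' conditions. This is the preprocessing step of the network reconstruction:
#' all pattern matching afterwards operates on the edge representation only,
#' which makes the method insensitive to the absolute expression scale
#' (scaling a profile by a positive factor leaves its representation
#' unchanged).
#'
#' @param x numeric gene x condition matrix (row names are gene identifiers;
#'   generated when absent), or a SummarizedExperiment whose first assay is
#'   used.
#' @return an [EdgeRepresentation-class].
#' @examples
#' em <- matrix(c(343, 314, 409), 1, dimnames = list("G1", NULL))
#' er <- edgeTransform(em)
#' round(angles(er))   # 138, 52
#' regulations(er)     # -1, +1
#' @export
edgeTransform <- function(x) {
  x <- .asExpressionMatrix(x)
  if (ncol(x) < 2L) stop("edgeTransform: need at least 2 conditions")
  M <- ncol(x)
  prev <- x[, -M, drop = FALSE]
  nxt <- x[, -1, drop = FALSE]
  ang <- fluctuationAngle(prev, next_ = nxt)
  reg <- regulationSign(prev, next_ = nxt)
  dim(ang) <- dim(reg) <- c(nrow(x), M - 1L)
  edgeIds <- paste0("e", seq_len(M - 1L))
  dimnames(ang) <- dimnames(reg) <- list(rownames(x), edgeIds)
  methods::new("EdgeRepresentation", geneIds = rownames(x),
               angles = ang, regulations = reg)
}
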