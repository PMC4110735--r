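#' Read a tab-separated expression matrix
#'
#' Expects a header line of condition identifiers and one row per gene with
#' the gene identifier in the first column. All expression cells must be
#' finite numbers; duplicated gene identifiers, non-numeric cells and
#' missing values are reported with their location.
#'
#' @param path file path.
#' @return numeric gene x condition matrix with dimnames.
#' @seealso [writeExpressionTsv()], [edgeTransform()]
#' @export
readExpressionTsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("expression file must have a header plus at least one gene row ",
         "and one condition column: ", path)
  genes <- df[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene identifiers: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1, ]
    stop(sprintf(
      "non-numeric or missing expression value at gene '%s', condition '%s'",
      genes[b[1]], colnames(vals)[b[2]]))
  }
  dimnames(num) <- list(genes, colnames(vals))
  num
}

#' Write an expression matrix as tab-separated text
#'
#' @param x numeric gene x condition matrix with dimnames.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeExpressionTsv <- function(x, path) {
  x <- .asExpressionMatrix(x)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gold-standard edge list (DREAM dialect)
#'
#' Three tab-separated columns: source gene, target gene, label in \{0, 1\}.
#' The directed list is symmetrised: an unordered pair is positive when
#' either direction carries label 1. Self-edges are dropped with a warning.
#' The gene universe is the set of genes mentioned in the file unless
#' `genes` supplies a larger one.
#'
#' @param path file path.
#' @param genes optional character vector fixing the gene universe.
#' @return a [GoldStandard-class].
#' @seealso [evaluateNetwork()]
#' @export
readGoldEdgelist <- function(path, genes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty gold-standard file: ", path)
    return(GoldStandard(if (is.null(genes)) character(0) else genes,
                        matrix(character(0), 0, 2)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L))
    stop(sprintf("malformed line %d in %s: expected 3 tab-separated fields",
                 which(nf != 3L)[1], path))
  m <- do.call(rbind, parts)
  lab <- m[, 3]
  if (!all(lab %in% c("0", "1")))
    stop(sprintf("malformed line %d in %s: label must be 0 or 1",
                 which(!lab %in% c("0", "1"))[1], path))
  universe <- sort(unique(c(m[, 1], m[, 2], genes)))
  self <- m[, 1] == m[, 2]
  if (any(self)) {
    warning(sum(self), " self-edge(s) dropped: ", path)
    m <- m[!self, , drop = FALSE]
    lab <- lab[!self]
  }
  posPairs <- m[lab == "1", 1:2, drop = FALSE]
  GoldStandard(universe, posPairs)
}

#' Write a gold standard as a DREAM-dialect edge list
#'
#' Positive pairs only, one per line, smaller identifier first, label 1.
#'
#' @param gold a [GoldStandard-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeGoldEdgelist <- function(gold, path) {
  stopifnot(methods::is(gold, "GoldStandard"))
  p <- gold@pairs
  writeLines(if (nrow(p)) paste(p[, 1], p[, 2], "1", sep = "\t")
             else character(0), path)
  invisible(path)
}

#' Write a signed network as a tab-separated edge list
#'
#' Columns: geneA, geneB, sign (+1/-1), support (combined support, 6 decimal
#' places). Each unordered pair appears once, in lexicographic pair order.
#'
#' @param net a [SignedNetwork-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @seealso [readSignedEdgelist()]
#' @export
writeSignedEdgelist <- function(net, path) {
  stopifnot(methods::is(net, "SignedNetwork"))
  A <- net@adjacency
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  g1 <- net@geneIds[idx[, 1]]
  g2 <- net@geneIds[idx[, 2]]
  lo <- pmin(g1, g2)
  hi <- pmax(g1, g2)
  ord <- order(lo, hi)
  rows <- sprintf("%s\t%s\t%d\t%.6f", lo[ord], hi[ord],
                  A[idx][ord], net@edgeScores[idx][ord])
  writeLines(c("geneA\tgeneB\tsign\tsupport", rows), path)
  invisible(path)
}

#' Read a signed edge list written by [writeSignedEdgelist()]
#'
#' @param path file path.
#' @param genes optional gene universe; defaults to the genes in the file.
#' @return a [SignedNetwork-class] with edge scores from the support column.
#' @export
readSignedEdgelist <- function(path, genes = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "integer", "numeric"))
  universe <- sort(unique(c(df$geneA, df$geneB, genes)))
  n <- length(universe)
  A <- matrix(0L, n, n, dimnames = list(universe, universe))
  S <- matrix(0, n, n, dimnames = list(universe, universe))
  if (nrow(df)) {
    i <- match(df$geneA, universe)
    j <- match(df$geneB, universe)
    A[cbind(i, j)] <- A[cbind(j, i)] <- df$sign
    S[cbind(i, j)] <- S[cbind(j, i)] <- df$support
  }
  methods::new("SignedNetwork", geneIds = universe, adjacency = A,
               edgeScores = S, theta = NA_real_)
}

#' Write a module table
#'
#' Tab-separated `gene<TAB>module` rows, module identifiers as produced by
#' [extractModules()] (decreasing size, then lexicographic smallest member).
#'
#' @param modules data.frame from [extractModules()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeModuleTable <- function(modules, path) {
  stopifnot(is.data.frame(modules), all(c("gene", "module") %in% names(modules)))
  utils::write.table(modules[, c("gene", "module")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
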