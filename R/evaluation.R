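#' F-beta score
#'
#' Weighted harmonic mean of precision and recall,
#' (1 + beta^2) P R / (beta^2 P + R). beta < 1 weighs precision higher
#' (beta = 0.5 is the usual precision-leaning choice for network inference,
#' where false edges are costlier than missed ones); beta > 1 weighs recall
#' higher. When both precision and recall are zero the score is defined as 0
#' with a warning.
#'
#' @param precision,recall fractions in \[0, 1\] (vectorised).
#' @param beta non-negative weight; default 0.5.
#' @return numeric vector of scores in \[0, 1\].
#' @examples
#' fBeta(0.7, 0.7, 2)        # 0.7: reduces to P when P == R
#' fBeta(1, 0.5, beta = 0.5) # 0.8333
#' @export
fBeta <- function(precision, recall, beta = 0.5) {
  if (length(beta) != 1L || !is.finite(beta) || beta < 0)
    stop("beta must be a single non-negative value")
  if (any(precision < 0 | precision > 1) || any(recall < 0 | recall > 1))
    stop("precision and recall must lie in [0, 1]")
  num <- (1 + beta^2) * precision * recall
  den <- beta^2 * precision + recall
  out <- ifelse(den == 0, 0, num / den)
  if (any(den == 0))
    warning("F-beta undefined at precision = recall = 0; reported as 0")
  out
}

#' Construct a gold standard from a set of positive pairs
#'
#' @param genes character vector, the gene universe.
#' @param pairs two-column character matrix or data.frame of positive pairs
#'   (order within a pair is ignored; duplicates collapse; self-pairs are
#'   dropped with a warning).
#' @return a [GoldStandard-class].
#' @export
GoldStandard <- function(genes, pairs) {
  genes <- as.character(genes)
  pairs <- as.matrix(pairs)
  if (nrow(pairs)) {
    pairs <- cbind(as.character(pairs[, 1]), as.character(pairs[, 2]))
    self <- pairs[, 1] == pairs[, 2]
    if (any(self)) {
      warning(sum(self), " self-pair(s) dropped from gold standard")
      pairs <- pairs[!self, , drop = FALSE]
    }
    lo <- pmin(pairs[, 1], pairs[, 2])
    hi <- pmax(pairs[, 1], pairs[, 2])
    pairs <- unique(cbind(lo, hi))
    dimnames(pairs) <- NULL
  } else {
    pairs <- matrix(character(0), 0, 2)
  }
  methods::new("GoldStandard", geneIds = genes, pairs = pairs)
}

# Shared threshold sweep. Scores and labels cover the full pair universe.
# Returns one row per distinct score, descending; predictions at each
# threshold include ties.
.sweepConfusion <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]
  labels <- labels[ord]
  P <- sum(labels)
  Nn <- sum(!labels)
  last <- cumsum(rle(scores)$lengths)   # index of last pair at each threshold
  tp <- cumsum(labels)[last]
  fp <- cumsum(!labels)[last]
  data.frame(threshold = scores[last], tp = tp, fp = fp,
             fn = P - tp, tn = Nn - fp)
}

.predScores <- function(pred, gold) {
  stopifnot(methods::is(gold, "GoldStandard"))
  if (nrow(gold@pairs) == 0L)
    stop("gold standard has no positive pairs; recall is undefined")
  universe <- gold@geneIds
  if (methods::is(pred, "SignedNetwork")) {
    bad <- setdiff(pred@geneIds, universe)
    if (length(bad))
      stop("predicted genes absent from the gold universe: ",
           paste(bad, collapse = ", "))
    S <- pred@edgeScores
    idx <- which(upper.tri(S), arr.ind = TRUE)
    pred <- data.frame(gene1 = pred@geneIds[idx[, 1]],
                       gene2 = pred@geneIds[idx[, 2]],
                       score = S[idx])
    pred <- pred[pred$score > 0, , drop = FALSE]
  }
  pred <- as.data.frame(pred)
  if (ncol(pred) < 3L)
    stop("a ranked prediction needs columns gene1, gene2, score")
  names(pred)[1:3] <- c("gene1", "gene2", "score")
  bad <- setdiff(unique(c(pred$gene1, pred$gene2)), universe)
  if (length(bad))
    stop("predicted genes absent from the gold universe: ",
         paste(bad, collapse = ", "))
  if (any(!is.finite(pred$score))) stop("prediction scores must be finite")
  if (anyDuplicated(.pairKeys(pred$gene1, pred$gene2)))
    stop("duplicate predicted pairs")
  n <- length(universe)
  idx <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  keys <- .pairKeys(universe[idx[, 1]], universe[idx[, 2]])
  scores <- numeric(length(keys))            # pairs absent from pred score 0
  m <- match(.pairKeys(pred$gene1, pred$gene2), keys)
  if (anyNA(m)) stop("predicted pairs contain self-pairs")
  scores[m] <- pred$score
  labels <- keys %in% .pairKeys(gold@pairs[, 1], gold@pairs[, 2])
  list(scores = scores, labels = labels)
}

#' Precision-recall and ROC curves of a ranked network prediction
#'
#' Sweeps the confidence threshold over all distinct score values in
#' descending order; pairs of the gold universe absent from the prediction
#' are ranked last with confidence 0. Precision-recall starts from the
#' highest-confidence prediction group (with an anchor at recall 0); the ROC
#' curve is anchored at (0, 0) and ends at (1, 1).
#'
#' @param pred a [SignedNetwork-class] (pairs scored by combined support) or
#'   a data.frame with columns gene1, gene2, score of unique unordered pairs.
#' @param gold a [GoldStandard-class]; its gene set defines the pair
#'   universe.
#' @return data.frame of curve points: `recall`, `precision` (and
#'   `threshold`) for [prCurve()]; `fpr`, `tpr` (and `threshold`) for
#'   [rocCurve()].
#' @seealso [curveAuc()], [evaluateNetwork()]
#' @export
prCurve <- function(pred, gold) {
  sl <- .predScores(pred, gold)
  cf <- .sweepConfusion(sl$scores, sl$labels)
  prec <- ifelse(cf$tp + cf$fp == 0, 1, cf$tp / (cf$tp + cf$fp))
  rec <- cf$tp / (cf$tp + cf$fn)
  data.frame(threshold = c(Inf, cf$threshold),
             recall = c(0, rec), precision = c(prec[1], prec))
}

#' @rdname prCurve
#' @export
rocCurve <- function(pred, gold) {
  sl <- .predScores(pred, gold)
  cf <- .sweepConfusion(sl$scores, sl$labels)
  data.frame(threshold = c(Inf, cf$threshold),
             fpr = c(0, cf$fp / (cf$fp + cf$tn)),
             tpr = c(0, cf$tp / (cf$tp + cf$fn)))
}

#' Trapezoidal area under a curve
#'
#' @param x,y coordinates of the curve points; x must be non-decreasing.
#'   A data.frame whose first two columns are x and y may be given as `x`.
#' @return the trapezoidal area.
#' @examples
#' curveAuc(c(0, 1), c(0, 1))  # 0.5
#' @export
curveAuc <- function(x, y = NULL) {
  if (is.null(y)) {
    stopifnot(is.data.frame(x), ncol(x) >= 2)
    y <- x[[2]]
    x <- x[[1]]
  }
  if (length(x) < 2L) stop("need at least 2 points")
  if (any(diff(x) < 0)) stop("x must be non-decreasing")
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Score a predicted network against a gold standard
#'
#' Ranks every pair of the gold universe by the network's combined support
#' (zero for non-edges; the edge sign is ignored for scoring), sweeps the
#' confidence threshold, and reports the areas under the precision-recall
#' and ROC curves together with the maximum and average F-beta along the
#' sweep.
#'
#' @param net a [SignedNetwork-class], or a ranked data.frame as accepted by
#'   [prCurve()].
#' @param gold a [GoldStandard-class] over the same gene identifiers;
#'   mismatched identifiers raise an error naming the offenders.
#' @param beta F-score weight; the default 0.5 emphasises precision.
#' @return an [EvalScores-class].
#' @examples
#' em <- rbind(G1 = c(1, 5, 2, 8), G2 = c(2, 6, 3, 9), G3 = c(9, 1, 7, 0))
#' net <- buildNetwork(buildCorrelogram(edgeTransform(em)))
#' gold <- GoldStandard(c("G1", "G2", "G3"), rbind(c("G1", "G2")))
#' evaluateNetwork(net, gold)
#' @export
evaluateNetwork <- function(net, gold, beta = 0.5) {
  sl <- .predScores(net, gold)
  cf <- .sweepConfusion(sl$scores, sl$labels)
  prec <- ifelse(cf$tp + cf$fp == 0, 1, cf$tp / (cf$tp + cf$fp))
  rec <- cf$tp / (cf$tp + cf$fn)
  pr <- data.frame(threshold = c(Inf, cf$threshold),
                   recall = c(0, rec), precision = c(prec[1], prec))
  roc <- data.frame(threshold = c(Inf, cf$threshold),
                    fpr = c(0, cf$fp / (cf$fp + cf$tn)),
                    tpr = c(0, cf$tp / (cf$tp + cf$fn)))
  num <- (1 + beta^2) * prec * rec
  den <- beta^2 * prec + rec
  fb <- ifelse(den == 0, 0, num / den)
  methods::new("EvalScores",
               aupr = curveAuc(pr$recall, pr$precision),
               auroc = curveAuc(roc$fpr, roc$tpr),
               fBetaMax = max(fb), fBetaAvg = mean(fb), beta = beta,
               prPoints = pr, rocPoints = roc)
}

#' @describeIn evaluateNetwork numeric summary of an [EvalScores-class].
#' @param scores an [EvalScores-class].
#' @export
evalSummary <- function(scores) {
  stopifnot(methods::is(scores, "EvalScores"))
  c(aupr = scores@aupr, auroc = scores@auroc,
    fBetaMax = scores@fBetaMax, fBetaAvg = scores@fBetaAvg,
    beta = scores@beta)
}
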