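#' Describe a synthetic co-regulation dataset
#'
#' Builds a [PatternSpec-class] with the generator's study conditions. The
#' defaults plant three 10-gene modules (one shifted, one scaled, one
#' inverted) over 15 conditions with 10 unstructured background genes and
#' mild measurement noise.
#'
#' @param nModules number of planted modules; default 3.
#' @param genesPerModule genes per module (>= 2); default 10.
#' @param nConditions conditions/time points (>= 3); default 15.
#' @param patternKinds character vector of module kinds, recycled to
#'   `nModules`; default `c("shifted", "scaled", "inverted")`.
#' @param alpha additive-offset magnitude in expression units; each shifted
#'   member's offset is drawn uniformly from \[-alpha, alpha\]. Default 25,
#'   small against the profile dynamic range (hundreds of units) so that
#'   shifting preserves the local pattern geometry.
#' @param betaScale multiplicative-factor bound (> 0); each scaled member's
#'   factor is drawn log-uniformly from \[1/betaScale, betaScale\]. Default 3,
#'   the "roughly three times larger" magnitude typical of scaled
#'   co-expression illustrations.
#' @param noiseSd additive Gaussian noise sd in expression units; default 10.
#' @param nBackgroundGenes independent unstructured genes; default 10.
#' @param seed master seed; every random choice in the generator derives
#'   from it, so equal specs yield identical datasets.
#' @return a [PatternSpec-class].
#' @seealso [generateDataset()]
#' @export
patternSpec <- function(nModules = 3, genesPerModule = 10, nConditions = 15,
                        patternKinds = c("shifted", "scaled", "inverted"),
                        alpha = 25, betaScale = 3, noiseSd = 10,
                        nBackgroundGenes = 10, seed = 1) {
  kinds <- rep_len(patternKinds, nModules)
  methods::new("PatternSpec", nModules = as.integer(nModules),
               genesPerModule = as.integer(genesPerModule),
               nConditions = as.integer(nConditions),
               patternKinds = kinds, alpha = alpha, betaScale = betaScale,
               noiseSd = noiseSd,
               nBackgroundGenes = as.integer(nBackgroundGenes),
               seed = as.integer(seed))
}

# Sub-seeds: all generator randomness flows from the master seed through
# this splitter, so any single profile is reproducible in isolation.
.subSeed <- function(seed, stream) {
  (as.integer(seed) * 48271 + as.integer(stream) * 16807) %% 2147483647L
}

#' Generate a base expression profile
#'
#' Two styles of base profile are produced, matching the two data regimes in
#' which the pattern transform operates:
#'
#' * `"fluctuating"`: a mean-reverting walk around zero (AR(1),
#'   autocorrelation 0.3, stationary sd 300), emulating log-ratio expression
#'   that swings through positive and negative values. Its edge angles
#'   spread broadly over \[0, 180\] degrees, which is what gives the method
#'   its specificity between unrelated genes.
#' * `"level"`: a positive baseline (level drawn from \[200, 600\],
#'   intensity-like units) drifting by a few percent per step, interrupted
#'   by a small number of extreme one-condition spikes (4-10 times the
#'   baseline, at most one of them negative) at non-adjacent interior
#'   conditions. Near-level edges sit close to the 45/135-degree diagonal,
#'   where reflection about the profile mean is visible to the negative
#'   similarity rule; the spikes carry the gene-specific signature that
#'   keeps unrelated level-style genes apart. The spike count is chosen so
#'   near-level edges remain a strict majority of the M-1 edges.
#'
#' Consecutive values are never equal (fluctuations are non-degenerate with
#' probability one; the continuous draws guarantee it).
#'
#' @param nConditions number of conditions (>= 3).
#' @param seed integer seed; equal seeds give identical profiles.
#' @param style `"fluctuating"` or `"level"`.
#' @return numeric vector of length `nConditions`.
#' @seealso [deriveMember()], [generateDataset()]
#' @export
makeBaseProfile <- function(nConditions, seed,
                            style = c("fluctuating", "level")) {
  style <- match.arg(style)
  if (nConditions < 3L) stop("nConditions must be >= 3")
  set.seed(seed)
  M <- as.integer(nConditions)
  if (style == "fluctuating") {
    phi <- 0.3; sd0 <- 300
    v <- numeric(M)
    v[1] <- stats::rnorm(1, 0, sd0)
    for (t in 2:M)
      v[t] <- phi * v[t - 1] + stats::rnorm(1, 0, sd0 * sqrt(1 - phi^2))
    v
  } else {
    m <- stats::runif(1, 200, 600)
    v <- m * exp(cumsum(stats::rnorm(M, 0, 0.05)))
    K <- M - 1L
    nSpikes <- max(0L, (K - K %/% 2L - 1L) %/% 2L)
    pos <- integer(0)
    cand <- 2:(M - 1L)
    for (i in seq_len(nSpikes)) {
      if (!length(cand)) break
      p <- if (length(cand) == 1L) cand else sample(cand, 1L)
      pos <- c(pos, p)
      cand <- setdiff(cand, (p - 1L):(p + 1L))
    }
    sgn <- rep(1, length(pos))
    if (length(pos) && stats::runif(1) < 0.5)
      sgn[sample.int(length(pos), 1L)] <- -1
    v[pos] <- m * stats::runif(length(pos), 4, 10) * sgn
    v
  }
}

#' Derive a co-regulated module member from a base profile
#'
#' * `shifted`: base + alpha (constant additive offset).
#' * `scaled`: base x betaFactor (constant positive multiplicative factor).
#' * `inverted`: reflection of the base about its mean, 2 mean(base) - base,
#'   which reverses every regulation sign.
#' * `mixed`: the reflection applied on a random contiguous window of
#'   conditions, so the member is positively co-regulated on part of the
#'   profile and negatively on the rest.
#'
#' Gaussian noise with sd `noiseSd` is added afterwards.
#'
#' @param base numeric base profile.
#' @param kind one of `"shifted"`, `"scaled"`, `"inverted"`, `"mixed"`.
#' @param alpha additive offset used for `shifted` (expression units).
#' @param betaFactor multiplicative factor used for `scaled` (> 0).
#' @param noiseSd additive noise sd (>= 0).
#' @param seed integer seed for the noise and the mixed window.
#' @return numeric profile of the same length as `base`.
#' @seealso [makeBaseProfile()], [generateDataset()]
#' @export
deriveMember <- function(base, kind, alpha = 0, betaFactor = 1,
                         noiseSd = 0, seed = 1) {
  if (!kind %in% c("shifted", "scaled", "inverted", "mixed"))
    stop("unknown pattern kind: ", kind)
  if (betaFactor <= 0) stop("betaFactor must be > 0")
  set.seed(seed)
  v <- switch(kind,
    shifted = base + alpha,
    scaled = base * betaFactor,
    inverted = 2 * mean(base) - base,
    mixed = {
      w <- sort(sample.int(length(base), 2L))
      out <- base
      out[w[1]:w[2]] <- 2 * mean(base) - base[w[1]:w[2]]
      out
    })
  v + stats::rnorm(length(base), 0, noiseSd)
}

#' Generate a synthetic dataset with planted co-regulation modules
#'
#' Each module is grown from an independent base profile; member 1 is the
#' base itself (plus noise) and the rest are derived per the module's
#' pattern kind. Shifted and scaled modules (and background genes) use
#' fluctuating log-ratio-like bases; inverted and mixed modules use
#' positive level-style bases, the regime in which reflection about the
#' mean registers as negative pattern similarity. In an inverted module the
#' even-numbered members are reflected and the odd-numbered ones follow the
#' base, so the module contains both positively and negatively co-regulated
#' pairs; a pair's ground-truth sign is the product of its members'
#' orientations. The ground-truth network is the union of within-module
#' cliques; background genes have no truth edges.
#'
#' @param spec a [PatternSpec-class].
#' @return a [SyntheticDataset-class].
#' @examples
#' sd1 <- generateDataset(patternSpec(seed = 7))
#' sd2 <- generateDataset(patternSpec(seed = 7))
#' identical(exprs(sd1), exprs(sd2))  # TRUE
#' @export
generateDataset <- function(spec) {
  stopifnot(methods::is(spec, "PatternSpec"))
  methods::validObject(spec)
  M <- spec@nConditions
  npm <- spec@genesPerModule
  N <- spec@nModules * npm + spec@nBackgroundGenes
  V <- matrix(0, N, M)
  labels <- integer(N)
  orient <- rep(1, N)
  gid <- sprintf("G%03d", seq_len(N))
  stream <- 0L
  g <- 0L
  for (mod in seq_len(spec@nModules)) {
    kind <- spec@patternKinds[mod]
    style <- if (kind %in% c("inverted", "mixed")) "level" else "fluctuating"
    stream <- stream + 1L
    base <- makeBaseProfile(M, .subSeed(spec@seed, stream), style)
    for (j in seq_len(npm)) {
      g <- g + 1L
      labels[g] <- mod
      stream <- stream + 1L
      s <- .subSeed(spec@seed, stream)
      set.seed(s)
      # per-member transform parameters, then the member itself
      a <- stats::runif(1, -spec@alpha, spec@alpha)
      b <- exp(stats::runif(1, -log(spec@betaScale), log(spec@betaScale)))
      memberKind <- kind
      if (j == 1L) {
        memberKind <- "shifted"; a <- 0
      } else if (kind == "inverted" && j %% 2L == 1L) {
        memberKind <- "shifted"   # odd members follow the base
      }
      if (memberKind == "inverted") orient[g] <- -1
      V[g, ] <- deriveMember(base, memberKind, alpha = a, betaFactor = b,
                             noiseSd = spec@noiseSd,
                             seed = .subSeed(s, 1L))
    }
  }
  for (b in seq_len(spec@nBackgroundGenes)) {
    g <- g + 1L
    stream <- stream + 1L
    s <- .subSeed(spec@seed, stream)
    base <- makeBaseProfile(M, s, "fluctuating")
    set.seed(.subSeed(s, 2L))
    V[g, ] <- base + stats::rnorm(M, 0, spec@noiseSd)
  }
  dimnames(V) <- list(gid, sprintf("T%02d", seq_len(M)))
  names(labels) <- names(orient) <- gid
  pairs <- do.call(rbind, lapply(seq_len(spec@nModules), function(mod) {
    members <- gid[labels == mod]
    if (length(members) < 2L) return(NULL)
    t(utils::combn(members, 2L))
  }))
  if (is.null(pairs)) pairs <- matrix(character(0), 0, 2)
  methods::new("SyntheticDataset", exprs = V,
               gold = GoldStandard(gid, pairs),
               moduleLabels = labels, orientations = orient, spec = spec)
}

#' Ground-truth signs of the planted pairs
#'
#' @param dataset a [SyntheticDataset-class].
#' @return data.frame with columns gene1, gene2, sign: every within-module
#'   pair with the product of its members' orientations (+1 or -1). For
#'   mixed-kind modules the orientation of every member is +1 by
#'   construction and the sign does not describe the window-inverted part.
#' @export
truthSigns <- function(dataset) {
  stopifnot(methods::is(dataset, "SyntheticDataset"))
  p <- dataset@gold@pairs
  data.frame(gene1 = p[, 1], gene2 = p[, 2],
             sign = dataset@orientations[p[, 1]] *
               dataset@orientations[p[, 2]],
             row.names = NULL)
}
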