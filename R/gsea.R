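# resolve a ranking argument to a named FCP vector in rank order
.rankedStats <- function(ranked, base = 10) {
  if (is(ranked, "DEProfile")) return(.fcpRanking(ranked, base = base))
  if (is.numeric(ranked) && !is.null(names(ranked))) {
    ord <- order(-ranked, names(ranked))
    return(ranked[ord])
  }
  stop("'ranked' must be a DEProfile or a named numeric vector")
}

# signed maximum deviation of the weighted KS running sum; extremes occur
# at hit positions (maxima) and immediately before them (minima)
.gseaES <- function(stats, hitIdx, exponent = 1) {
  N <- length(stats)
  n <- length(hitIdx)
  if (n == 0L) stop("empty gene set")
  if (n >= N) stop("gene set must be a proper subset of the ranking")
  pos <- sort(hitIdx)
  w <- abs(stats[pos])^exponent
  NR <- sum(w)
  if (NR == 0) {        # all hit scores zero: fall back to equal weights
    w <- rep(1, n)
    NR <- n
  }
  cw <- cumsum(w)
  miss <- (pos - seq_len(n)) / (N - n)
  tops <- cw / NR - miss
  bots <- (cw - w) / NR - miss
  hi <- max(tops)
  lo <- min(bots)
  if (abs(hi) >= abs(lo)) hi else lo
}

#' Preranked gene-set enrichment of one gene set
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment of `geneSet` against
#' an FCP-ranked gene list. Walking down the ranking, hits increment the
#' running sum proportionally to `|FCP|^weightExponent` (normalised to sum
#' 1 over the set) and misses decrement it by `1 / (N - n)`; the
#' enrichment score (ES) is the signed maximum deviation from zero. The
#' p-value is a two-sided gene-label permutation test,
#' `(1 + #\{|ES*| >= |ES|\}) / (1 + nPerm)`, deterministic given `seed`.
#'
#' @param geneSet Character vector of genes, a subset of the ranked list.
#' @param ranked A [DEProfile-class] (ranked by FCP internally) or a named
#'   numeric score vector.
#' @param weightExponent Hit-weight exponent (default 1; 0 gives the
#'   unweighted KS statistic).
#' @param nPerm Number of gene-label permutations (>= 100).
#' @param seed Integer seed for the permutations; `NULL` uses the current
#'   RNG stream.
#' @param base Logarithm base when `ranked` is a profile.
#' @return List with elements `es`, `pvalue` and `nPerm`.
#' @export
gseaEnrichment <- function(geneSet, ranked, weightExponent = 1,
                           nPerm = 1000, seed = NULL, base = 10) {
  stats <- .rankedStats(ranked, base = base)
  geneSet <- unique(as.character(geneSet))
  if (length(geneSet) == 0L) stop("empty gene set")
  if (nPerm < 100) stop("nPerm must be at least 100")
  hitIdx <- match(geneSet, names(stats))
  if (anyNA(hitIdx))
    stop(sprintf("gene '%s' absent from the ranked list",
                 geneSet[which(is.na(hitIdx))[1]]))
  es <- .gseaES(stats, hitIdx, exponent = weightExponent)
  N <- length(stats)
  n <- length(hitIdx)
  permEs <- .withSeed(seed, vapply(seq_len(nPerm), function(b) {
    .gseaES(stats, sample.int(N, n), exponent = weightExponent)
  }, 0))
  list(es = es,
       pvalue = (1 + sum(abs(permEs) >= abs(es))) / (1 + nPerm),
       nPerm = nPerm)
}

#' GSEA feature vector of one exposure (GSEA baseline)
#'
#' Describes an exposure by the enrichment p-values of its deregulation
#' signature against the FCP-ranked gene lists of all other exposures of
#' the same biological system. The vector is ordered by sorted exposure
#' id, the target itself excluded; permutation seeds are derived per
#' reference so entries are order-independent.
#'
#' @param targetId Exposure id; must name an element of `profiles`.
#' @param profiles Named list of [DEProfile-class] objects for one system
#'   (>= 2 entries).
#' @param networkGenes Genes the selection is restricted to; defaults to
#'   all genes of the target profile.
#' @param geneSet Optional explicit gene set overriding the selection.
#' @param nUp,nDown Selection sizes passed to [selectDeregulated()].
#' @param weightExponent,nPerm,seed,base Passed to [gseaEnrichment()].
#' @return Named numeric vector of p-values over the other exposures.
#' @export
gseaVector <- function(targetId, profiles, networkGenes = NULL,
                       geneSet = NULL, nUp = 100, nDown = 100,
                       weightExponent = 1, nPerm = 1000, seed = NULL,
                       base = 10) {
  if (is.null(names(profiles)))
    names(profiles) <- vapply(profiles, exposureId, "")
  if (length(profiles) < 2L)
    stop("need at least two exposures in the system")
  if (!targetId %in% names(profiles))
    stop(sprintf("unknown exposure '%s'", targetId))
  if (is.null(geneSet)) {
    target <- profiles[[targetId]]
    networkGenes <- networkGenes %||% profileTable(target)$gene
    geneSet <- selectedGenes(
      selectDeregulated(target, networkGenes, nUp, nDown, base = base))
  }
  others <- sort(setdiff(names(profiles), targetId))
  vapply(stats::setNames(others, others), function(r) {
    s <- if (is.null(seed)) NULL else .deriveSeed(seed, targetId, r)
    gseaEnrichment(geneSet, profiles[[r]], weightExponent = weightExponent,
                   nPerm = nPerm, seed = s, base = base)$pvalue
  }, 0)
}
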