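#' Pairwise similarity or distance between exposure vectors
#'
#' @param vectors Numeric matrix, one exposure per row.
#' @param metric `"cosine_distance"` (diagonal 0, entries in \[0, 2\],
#'   all-zero rows handled as in [cosineDistance()]) or `"pearson"`
#'   (sample correlation, diagonal 1).
#' @return Symmetric matrix with exposure ids as dimnames.
#' @export
pairwiseSimilarity <- function(vectors,
                               metric = c("cosine_distance", "pearson")) {
  metric <- match.arg(metric)
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2L) stop("need at least two vectors")
  if (metric == "cosine_distance") return(.cosineDistMatrix(vectors))
  C <- stats::cor(t(vectors))
  diag(C) <- 1
  dimnames(C) <- list(rownames(vectors), rownames(vectors))
  C
}

#' Cluster compounds from a distance matrix
#'
#' Ward-linkage hierarchical clustering on a (cosine) distance matrix, cut
#' to `k` clusters; deterministic given the matrix.
#'
#' @param dist Symmetric distance matrix with zero diagonal (e.g. from
#'   `pairwiseSimilarity(v, "cosine_distance")`).
#' @param k Number of clusters (1 <= k <= number of exposures).
#' @return Named integer vector, exposure -> cluster id.
#' @export
clusterCompounds <- function(dist, k) {
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (k < 1 || k > n) stop(sprintf("k must lie in [1, %d]", n))
  if (k == n) {
    nm <- rownames(dist) %||% as.character(seq_len(n))
    return(stats::setNames(seq_len(n), nm))
  }
  stats::cutree(stats::hclust(stats::as.dist(dist), method = "ward.D2"),
                k = k)
}

#' Jaccard overlap between two compound clusterings
#'
#' Compares cluster member sets of two systems by the Jaccard index, finds
#' the best-matching cluster per row, and reports the exposures of
#' best-matching pairs with overlap at least `threshold` as the
#' cross-system consistent set.
#'
#' @param a,b Named cluster assignments (exposure -> cluster id), e.g.
#'   from [clusterCompounds()]; the exposure universes must overlap.
#' @param threshold Minimal Jaccard index for the consistent set
#'   (default 0.5).
#' @return List with `jaccard` (cluster-by-cluster matrix), `best_match`
#'   (`data.frame` per cluster of `a`) and `consistent` (character vector
#'   of exposures).
#' @export
clusterOverlap <- function(a, b, threshold = 0.5) {
  if (length(intersect(names(a), names(b))) == 0L)
    stop("clusterings share no exposures")
  ga <- split(names(a), a)
  gb <- split(names(b), b)
  J <- matrix(0, length(ga), length(gb),
              dimnames = list(names(ga), names(gb)))
  for (i in seq_along(ga)) {
    for (j in seq_along(gb)) {
      J[i, j] <- length(intersect(ga[[i]], gb[[j]])) /
        length(union(ga[[i]], gb[[j]]))
    }
  }
  bestIdx <- apply(J, 1L, which.max)
  best <- data.frame(cluster_a = names(ga),
                     cluster_b = names(gb)[bestIdx],
                     jaccard = J[cbind(seq_along(ga), bestIdx)],
                     stringsAsFactors = FALSE)
  consistent <- sort(unique(unlist(lapply(which(best$jaccard >= threshold),
    function(i) intersect(ga[[i]], gb[[bestIdx[i]]])))))
  list(jaccard = J, best_match = best,
       consistent = as.character(consistent))
}

#' Class-retrieval curve over top-x neighbourhoods
#'
#' For each labelled compound, all other compounds are ranked by Pearson
#' similarity of their feature vectors; for every cutoff x the number of
#' same-class compounds in the top x is divided by the total class size in
#' the dataset (excluding the query itself, which cannot retrieve itself).
#' Per-compound scores are summed over compounds, giving one curve per
#' method, compared by trapezoidal AUC (higher is better).
#'
#' @param vectors A matrix (rows = exposures) or a named list of such
#'   matrices, one per method.
#' @param classLabels Named character vector, exposure -> class;
#'   unlabelled exposures are dropped.
#' @param xMax Largest cutoff; defaults to the number of labelled
#'   compounds minus one.
#' @return List with `x`, `scores` (matrix x-by-method) and `auc`.
#' @export
classRetrievalCurve <- function(vectors, classLabels, xMax = NULL) {
  if (is.matrix(vectors) || is.data.frame(vectors))
    vectors <- list(method = as.matrix(vectors))
  labeled <- intersect(rownames(vectors[[1L]]),
                       names(classLabels)[!is.na(classLabels)])
  if (length(labeled) < 2L)
    stop("need at least two labelled compounds")
  xMax <- min(xMax %||% (length(labeled) - 1L), length(labeled) - 1L)
  x <- seq_len(xMax)
  scores <- sapply(vectors, function(V) {
    S <- pairwiseSimilarity(V[labeled, , drop = FALSE], "pearson")
    curve <- numeric(xMax)
    for (cpd in labeled) {
      others <- setdiff(labeled, cpd)
      ord <- others[order(-S[cpd, others], others)]
      nClass <- sum(classLabels[others] == classLabels[cpd])
      if (nClass == 0L) next
      hits <- cumsum(classLabels[ord] == classLabels[cpd])
      curve <- curve + hits[x] / nClass
    }
    curve
  })
  scores <- matrix(scores, nrow = xMax,
                   dimnames = list(NULL, names(vectors)))
  list(x = x, scores = scores,
       auc = apply(scores, 2L, function(y) .aucTrapezoid(x, y)))
}

#' Levenshtein edit distance
#'
#' Standard unit-cost edit distance (insertions, deletions,
#' substitutions), computed with `utils::adist`. Vectorised elementwise
#' over `a` and `b`.
#'
#' @param a,b Character vectors (recycled to common length).
#' @return Integer vector of distances.
#' @export
#' @examples
#' levenshteinDistance("kitten", "sitting")  # 3
levenshteinDistance <- function(a, b) {
  as.integer(mapply(function(x, y) utils::adist(x, y), a, b))
}

#' Reference ranking of exposure pairs
#'
#' Ranks all unordered exposure pairs by ascending distance: Levenshtein
#' distance when `x` is a named character vector of structure strings,
#' cosine distance between rows when `x` is a numeric descriptor (or
#' feature-vector) matrix. Ties receive their average rank. The same
#' function produces both the structure-based reference ranking and the
#' method rankings from feature vectors.
#'
#' @param x Named character vector of structure strings, or a numeric
#'   matrix with exposures as rows. Exposures with `NA` annotation are
#'   excluded.
#' @return `data.frame` with columns `a`, `b`, `distance`, `rank`, sorted
#'   by rank.
#' @export
referencePairRanking <- function(x) {
  if (is.character(x)) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) stop("need at least two annotated exposures")
    ids <- sort(names(x))
    D <- utils::adist(x[ids])
    dimnames(D) <- list(ids, ids)
  } else {
    x <- as.matrix(x)
    x <- x[rowSums(is.na(x)) == 0L, , drop = FALSE]
    if (nrow(x) < 2L) stop("need at least two annotated exposures")
    ids <- sort(rownames(x))
    D <- .cosineDistMatrix(x[ids, , drop = FALSE])
  }
  idx <- which(upper.tri(D), arr.ind = TRUE)
  out <- data.frame(a = ids[idx[, 1L]], b = ids[idx[, 2L]],
                    distance = D[idx], stringsAsFactors = FALSE)
  out$rank <- rank(out$distance, ties.method = "average")
  out[order(out$rank, out$a, out$b), , drop = FALSE]
}

#' Agreement of a method's pair ranking with a reference ranking
#'
#' Two curves compare a feature-vector-based pair ranking with a
#' structure-based reference over the same pair universe. The
#' rank-difference curve takes, for each x, the mean absolute rank
#' difference over the method's top-x pairs (AUC: lower is better). The
#' Jaccard curve is the overlap of the two top-x pair sets (AUC: higher is
#' better). The absolute rank differences of the method's top 20 pairs are
#' retained for density reporting. Both x grids are truncated to the
#' number of available pairs.
#'
#' @param method,reference Pair rankings from [referencePairRanking()]
#'   over the identical pair set.
#' @param xDiff,xJac Cutoff grids (defaults 2:200 and 1:1000).
#' @return List with `x_diff`, `rank_difference`, `auc_rank_difference`,
#'   `x_jac`, `jaccard`, `auc_jaccard`, `top20_rank_difference`.
#' @export
rankAgreement <- function(method, reference, xDiff = 2:200,
                          xJac = 1:1000) {
  key <- function(d) paste(pmin(d$a, d$b), pmax(d$a, d$b), sep = "\r")
  km <- key(method)
  kr <- key(reference)
  if (!setequal(km, kr)) stop("pair universes differ")
  npairs <- length(km)
  if (npairs < 2L) stop("need at least two pairs")
  refRank <- stats::setNames(reference$rank, kr)
  ordM <- order(method$rank, km)        # deterministic within ties
  ordR <- order(reference$rank, kr)
  diffs <- unname(abs(method$rank[ordM] - refRank[km[ordM]]))
  xDiff <- xDiff[xDiff <= npairs]
  rdCurve <- cumsum(diffs)[xDiff] / xDiff
  xJac <- xJac[xJac <= npairs]
  topM <- km[ordM]
  topR <- kr[ordR]
  jacCurve <- vapply(xJac, function(x) {
    inter <- length(intersect(topM[seq_len(x)], topR[seq_len(x)]))
    inter / (2 * x - inter)
  }, 0)
  list(x_diff = xDiff, rank_difference = unname(rdCurve),
       auc_rank_difference = .aucTrapezoid(xDiff, rdCurve),
       x_jac = xJac, jaccard = jacCurve,
       auc_jaccard = .aucTrapezoid(xJac, jacCurve),
       top20_rank_difference = unname(utils::head(diffs, 20L)))
}

#' Match query exposures to candidates across datasets
#'
#' For every pair of a query system and a candidate system, candidates are
#' ranked by ascending cosine distance to each query's community
#' fingerprint; per query-candidate pair the mean rank across system
#' pairs is taken, and the candidate with the minimal mean rank (ties
#' broken by candidate id) is the best match. Both datasets must be
#' fingerprinted against the same community partition.
#'
#' @param queryVectors,candidateVectors Named lists (one element per
#'   biological system) of fingerprint matrices with exposures as rows and
#'   identical community columns.
#' @return List with `mean_rank` (query-by-candidate matrix) and `best`
#'   (`data.frame` with `query`, `best_match`, `mean_rank`).
#' @export
crossDatasetMatch <- function(queryVectors, candidateVectors) {
  all <- c(queryVectors, candidateVectors)
  refCols <- colnames(all[[1L]])
  same <- vapply(all, function(m) {
    ncol(m) == length(refCols) && identical(colnames(m), refCols)
  }, TRUE)
  if (!all(same))
    stop("partition mismatch: fingerprints span different communities")
  queries <- rownames(queryVectors[[1L]])
  cands <- rownames(candidateVectors[[1L]])
  acc <- matrix(0, length(queries), length(cands),
                dimnames = list(queries, cands))
  npairs <- 0L
  for (Q in queryVectors) {
    for (C in candidateVectors) {
      npairs <- npairs + 1L
      for (q in queries) {
        d <- vapply(cands,
                    function(cc) cosineDistance(Q[q, ], C[cc, ]), 0)
        acc[q, ] <- acc[q, ] + rank(d, ties.method = "average")
      }
    }
  }
  meanRank <- acc / npairs
  best <- data.frame(
    query = queries,
    best_match = vapply(queries, function(q) {
      cands[order(meanRank[q, ], cands)][1L]
    }, ""),
    mean_rank = vapply(queries, function(q) min(meanRank[q, ]), 0),
    stringsAsFactors = FALSE, row.names = NULL)
  list(mean_rank = meanRank, best = best)
}
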