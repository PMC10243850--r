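#' Binary-edge distance between layers
#'
#' Compares layers on edge presence only (weights are ignored at this
#' stage; they first matter during merging). For each layer pair, three
#' components are computed on the binary edge sets and summed with equal
#' weight: the Jaccard distance, a simple-matching-coefficient (SMC)
#' distance over the union-of-all-layers edge universe, and one minus the
#' fraction of shared edges. The summed matrix is min-max scaled over its
#' off-diagonal entries into \[0, 1\] (all-equal off-diagonals scale to 0).
#'
#' The SMC universe is the union of binary edges over all layers being
#' compared, not all `N (N - 1) / 2` gene pairs: the all-pairs variant is
#' dominated by shared absences on sparse layers. The shared-fraction
#' denominator defaults to `min(|E_i|, |E_j|)` (containment); with `union`
#' the component duplicates Jaccard.
#'
#' @param layers List of [LayerNetwork-class] objects (>= 2), each with at
#'   least one edge.
#' @param sharedDenominator One of `"min"`, `"mean"`, `"union"`.
#' @return A [LayerDistanceMatrix-class].
#' @export
binaryLayerDistance <- function(layers,
                                sharedDenominator = c("min", "mean",
                                                      "union")) {
  sharedDenominator <- match.arg(sharedDenominator)
  if (length(layers) < 2L) stop("need at least two layers")
  nm <- vapply(layers, networkName, "")
  if (anyDuplicated(nm)) stop("layer names must be unique")
  keys <- lapply(layers, function(L) {
    e <- networkEdges(L)
    if (nrow(e) == 0L)
      stop(sprintf("layer '%s' has no edges", networkName(L)))
    paste(e$gene_a, e$gene_b, sep = "\r")
  })
  U <- length(unique(unlist(keys, use.names = FALSE)))
  n <- length(layers)
  jac <- smc <- shr <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ni <- length(keys[[i]])
      nj <- length(keys[[j]])
      inter <- length(intersect(keys[[i]], keys[[j]]))
      uni <- ni + nj - inter
      jac[i, j] <- jac[j, i] <- 1 - inter / uni
      smc[i, j] <- smc[j, i] <- 1 - (inter + (U - uni)) / U
      denom <- switch(sharedDenominator,
                      min = min(ni, nj),
                      mean = (ni + nj) / 2,
                      union = uni)
      shr[i, j] <- shr[j, i] <- 1 - inter / denom
    }
  }
  raw <- jac + smc + shr
  off <- raw[upper.tri(raw)]
  rng <- range(off)
  D <- if (diff(rng) > 0) (raw - rng[1]) / diff(rng) else raw * 0
  diag(D) <- 0
  new("LayerDistanceMatrix", layerNames = nm, D = unname(D),
      components = list(jaccard = jac, smc = smc, shared_fraction = shr),
      universeSize = U)
}

#' Cluster layers by their binary-edge distance
#'
#' Ward-linkage agglomerative clustering (equivalent to scipy's
#' `linkage(method = "ward")`, i.e. `hclust` `"ward.D2"`) on the combined
#' layer distance matrix, cut to exactly `k` clusters. Deterministic given
#' the matrix.
#'
#' @param dist A [LayerDistanceMatrix-class].
#' @param k Number of clusters (1 <= k <= number of layers).
#' @return Named integer vector mapping layer name to cluster id (1-based).
#' @export
clusterLayers <- function(dist, k = 3) {
  stopifnot(is(dist, "LayerDistanceMatrix"))
  n <- length(dist@layerNames)
  if (k < 1 || k > n)
    stop(sprintf("k must lie in [1, %d]", n))
  D <- dist@D
  dimnames(D) <- list(dist@layerNames, dist@layerNames)
  if (k == n)
    return(stats::setNames(seq_len(n), dist@layerNames))
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Merge layers by median-aligned summation
#'
#' Each layer's edge weights are multiplied by
#' `targetMedian / median(weights)` so all layers share the same median
#' weight, then summed over the union of edges (an edge absent from a
#' layer contributes 0). The result is not yet range-scaled.
#'
#' @param layers List of [LayerNetwork-class] objects, each with >= 1 edge.
#' @param targetMedian Common median the layers are aligned to
#'   (default 0.5, the midpoint of the scaled weight range; only relative
#'   weights matter downstream).
#' @param name Name for the merged layer.
#' @return A [LayerNetwork-class] over the union of nodes and edges.
#' @export
mergeNetworks <- function(layers, targetMedian = 0.5, name = "merged") {
  if (length(layers) == 0L) stop("need at least one layer")
  if (targetMedian <= 0) stop("targetMedian must be positive")
  keys <- character()
  wts <- numeric()
  nodes <- character()
  for (L in layers) {
    e <- networkEdges(L)
    if (nrow(e) == 0L)
      stop(sprintf("layer '%s' has no edges", networkName(L)))
    f <- targetMedian / stats::median(e$weight)
    keys <- c(keys, paste(e$gene_a, e$gene_b, sep = "\r"))
    wts <- c(wts, e$weight * f)
    nodes <- union(nodes, networkNodes(L))
  }
  agg <- rowsum(wts, keys)
  pair <- .splitKey(rownames(agg))
  LayerNetwork(name,
               data.frame(gene_a = pair$a, gene_b = pair$b,
                          weight = as.numeric(agg[, 1]),
                          stringsAsFactors = FALSE),
               nodes = nodes)
}

#' Fuse layers hierarchically into a prior network
#'
#' Two-stage, data-driven merge. Stage 1: layers within each cluster (by
#' default, Ward clusters of the binary-edge distance) are median-aligned,
#' summed and rescaled to (0, 1]. Stage 2: the per-cluster networks are
#' merged the same way, and the final weights are rescaled to (0, 1] by
#' division by the maximum (consistent with the per-layer scaling).
#' The node set and edge set of the result are the unions over all input
#' layers, and the merge is invariant to layer order within a cluster.
#'
#' @param layers List of [LayerNetwork-class] objects.
#' @param clustering Optional named integer vector (layer name -> cluster
#'   id), e.g. from [clusterLayers()]. When `NULL` it is computed from
#'   [binaryLayerDistance()] with `min(k, n_layers)` clusters.
#' @param k Number of layer clusters used when `clustering` is `NULL`
#'   (default 3).
#' @param targetMedian Median used by [mergeNetworks()] at both stages.
#' @param scaleInputs Apply [scaleLayerWeights()] to every input layer
#'   first (default `TRUE`, matching the pipeline order: build, scale,
#'   fuse).
#' @param sharedDenominator Passed to [binaryLayerDistance()].
#' @return A [PriorNetwork-class]; `provenance()` records the layer
#'   clusters, merge steps and scaling constants.
#' @export
fuseLayers <- function(layers, clustering = NULL, k = 3,
                       targetMedian = 0.5, scaleInputs = TRUE,
                       sharedDenominator = "min") {
  if (length(layers) == 0L) stop("need at least one layer")
  nm <- vapply(layers, networkName, "")
  names(layers) <- nm
  if (scaleInputs) layers <- lapply(layers, scaleLayerWeights)
  if (is.null(clustering)) {
    clustering <- if (length(layers) == 1L)
      stats::setNames(1L, nm)
    else
      clusterLayers(binaryLayerDistance(layers, sharedDenominator),
                    k = min(k, length(layers)))
  }
  if (!all(nm %in% names(clustering)))
    stop("clustering must cover every layer")
  clustering <- clustering[nm]
  steps <- list()
  clusterNets <- lapply(split(nm, clustering), function(members) {
    net <- mergeNetworks(layers[members], targetMedian,
                         name = paste(members, collapse = "+"))
    steps[[length(steps) + 1L]] <<- list(stage = 1L, members = members,
                                         max_weight =
                                           max(networkEdges(net)$weight))
    scaleLayerWeights(net)
  })
  final <- if (length(clusterNets) == 1L) clusterNets[[1L]] else
    mergeNetworks(clusterNets, targetMedian, name = "prior")
  steps[[length(steps) + 1L]] <-
    list(stage = 2L, members = vapply(clusterNets, networkName, ""),
         max_weight = max(networkEdges(final)$weight))
  final <- scaleLayerWeights(final)
  new("PriorNetwork", name = "prior", nodes = networkNodes(final),
      edges = networkEdges(final),
      provenance = list(layerClusters = clustering,
                        targetMedian = targetMedian,
                        scaling = "division-by-max",
                        sharedDenominator = sharedDenominator,
                        steps = steps))
}
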