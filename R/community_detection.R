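#' Partition the prior network into communities
#'
#' Agglomerative clustering on the network's weighted adjacency: connected
#' gene pairs are at distance `1 - weight`, unconnected pairs at the
#' maximal distance 1, and the dendrogram is cut at `distanceThreshold`
#' (clusters are the groups joined at merge heights <= the threshold).
#' Average linkage is the default: on dense weighted graphs it yields the
#' intended regime of many small communities without the chaining of
#' single linkage. Deterministic given the network.
#'
#' The dense gene-by-gene distance matrix is materialised, which is
#' appropriate for networks up to a few thousand genes.
#'
#' @param prior A [PriorNetwork-class] (or any [LayerNetwork-class]) with
#'   weights in (0, 1].
#' @param distanceThreshold Cut height in (0, 1] (default 0.5).
#' @param linkage One of `"average"`, `"complete"`, `"single"`.
#' @return A [CommunityPartition-class] over all network nodes, community
#'   ids 0-based in order of first appearance along the sorted gene list.
#' @export
detectCommunities <- function(prior, distanceThreshold = 0.5,
                              linkage = c("average", "complete",
                                          "single")) {
  stopifnot(is(prior, "LayerNetwork"))
  linkage <- match.arg(linkage)
  if (distanceThreshold <= 0 || distanceThreshold > 1)
    stop("distanceThreshold must lie in (0, 1]")
  nodes <- sort(networkNodes(prior))
  n <- length(nodes)
  if (n == 0L) stop("network has no nodes")
  if (n == 1L)
    return(new("CommunityPartition",
               assignment = stats::setNames(0L, nodes)))
  e <- networkEdges(prior)
  D <- matrix(1, n, n, dimnames = list(nodes, nodes))
  if (nrow(e)) {
    i <- match(e$gene_a, nodes)
    j <- match(e$gene_b, nodes)
    D[cbind(i, j)] <- 1 - e$weight
    D[cbind(j, i)] <- 1 - e$weight
  }
  diag(D) <- 0
  hc <- stats::hclust(stats::as.dist(D), method = linkage)
  # guard against floating-point jitter breaking cutree's monotone check
  hc$height <- cummax(hc$height)
  cl <- stats::cutree(hc, h = distanceThreshold)
  new("CommunityPartition",
      assignment = stats::setNames(match(cl, unique(cl)) - 1L, nodes))
}

#' Summary statistics of a community partition
#'
#' @param partition A [CommunityPartition-class].
#' @return List with `n_communities`, `mean_size`, `min_size`, `max_size`
#'   and `size_histogram` (a table of community sizes).
#' @export
#' @examples
#' p <- new("CommunityPartition",
#'          assignment = setNames(c(0L, 0L, 0L, 1L, 1L), letters[1:5]))
#' partitionStats(p)$mean_size
partitionStats <- function(partition) {
  stopifnot(is(partition, "CommunityPartition"))
  sizes <- communitySizes(partition)
  list(n_communities = length(sizes),
       mean_size = length(partition@assignment) / length(sizes),
       min_size = min(sizes),
       max_size = max(sizes),
       size_histogram = table(sizes))
}
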