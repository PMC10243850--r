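#' @rdname LayerNetwork-class
setMethod("networkName", "LayerNetwork", function(x) x@name)

#' @rdname LayerNetwork-class
setMethod("networkNodes", "LayerNetwork", function(x) x@nodes)

#' @rdname LayerNetwork-class
setMethod("networkEdges", "LayerNetwork", function(x) x@edges)

#' @rdname LayerNetwork-class
setMethod("nNodes", "LayerNetwork", function(x) length(x@nodes))

#' @rdname LayerNetwork-class
setMethod("nEdges", "LayerNetwork", function(x) nrow(x@edges))

#' @rdname networkDensity
setMethod("networkDensity", "LayerNetwork", function(x, nEdges) {
  networkDensity(length(x@nodes), nrow(x@edges))
})

#' @rdname networkDensity
setMethod("networkDensity", "numeric", function(x, nEdges) {
  if (x < 2) stop("need at least two nodes")
  2 * nEdges / (x * (x - 1))
})

#' @rdname PriorNetwork-class
setMethod("provenance", "PriorNetwork", function(x) x@provenance)

#' @rdname CommunityPartition-class
setMethod("communityAssignment", "CommunityPartition",
          function(x) x@assignment)

#' @rdname CommunityPartition-class
setMethod("communitySizes", "CommunityPartition", function(x) {
  tab <- table(x@assignment)
  stats::setNames(as.integer(tab), names(tab))
})

#' @rdname CommunityPartition-class
setMethod("nCommunities", "CommunityPartition", function(x) {
  length(unique(x@assignment))
})

#' @rdname DEProfile-class
setMethod("exposureId", "DEProfile", function(x) x@exposure)

#' @rdname DEProfile-class
setMethod("systemId", "DEProfile", function(x) x@system)

#' @rdname DEProfile-class
setMethod("profileTable", "DEProfile", function(x) x@table)

#' @rdname fcpScores
setMethod("fcpScores", "DEProfile", function(x, base = 10) {
  stats::setNames(fcpScore(x@table$logFC, x@table$pvalue, base = base),
                  x@table$gene)
})

#' @rdname GeneSelection-class
setMethod("upGenes", "GeneSelection", function(x) x@up)

#' @rdname GeneSelection-class
setMethod("downGenes", "GeneSelection", function(x) x@down)

#' @rdname GeneSelection-class
setMethod("selectedGenes", "GeneSelection", function(x) c(x@up, x@down))

#' @rdname LayerDistanceMatrix-class
setMethod("distanceMatrix", "LayerDistanceMatrix", function(x) {
  D <- x@D
  dimnames(D) <- list(x@layerNames, x@layerNames)
  D
})

#' @rdname LayerDistanceMatrix-class
setMethod("distanceComponents", "LayerDistanceMatrix",
          function(x) x@components)

setMethod("show", "LayerNetwork", function(object) {
  cat(sprintf("LayerNetwork '%s': %d nodes, %d edges\n", object@name,
              length(object@nodes), nrow(object@edges)))
  if (nrow(object@edges))
    cat(sprintf("  weight range [%.4g, %.4g]\n",
                min(object@edges$weight), max(object@edges$weight)))
})

setMethod("show", "PriorNetwork", function(object) {
  cat(sprintf("PriorNetwork: %d nodes, %d edges, density %.3f\n",
              length(object@nodes), nrow(object@edges),
              networkDensity(object)))
  pv <- object@provenance
  if (!is.null(pv$layerClusters))
    cat(sprintf("  fused from %d layers in %d clusters\n",
                length(pv$layerClusters),
                length(unique(pv$layerClusters))))
})

setMethod("show", "CommunityPartition", function(object) {
  s <- partitionStats(object)
  cat(sprintf(
    "CommunityPartition: %d genes in %d communities (mean size %.1f)\n",
    length(object@assignment), s$n_communities, s$mean_size))
})

setMethod("show", "DEProfile", function(object) {
  cat(sprintf("DEProfile %s on %s: %d genes\n", object@exposure,
              object@system, nrow(object@table)))
})

setMethod("show", "GeneSelection", function(object) {
  cat(sprintf("GeneSelection: %d up, %d down\n", length(object@up),
              length(object@down)))
})

setMethod("show", "LayerDistanceMatrix", function(object) {
  cat(sprintf(
    "LayerDistanceMatrix over %d layers (binary edge universe: %d pairs)\n",
    length(object@layerNames), object@universeSize))
})
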