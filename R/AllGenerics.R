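#' @rdname LayerNetwork-class
#' @param x,object A network, partition, profile or selection object.
#' @export
setGeneric("networkName", function(x) standardGeneric("networkName"))

#' @rdname LayerNetwork-class
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname LayerNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname LayerNetwork-class
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname LayerNetwork-class
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' Edge density of a network
#'
#' Fraction of realised gene pairs, `2 E / (N (N - 1))`. Either pass a
#' network object, or the node and edge counts directly.
#'
#' @param x A [LayerNetwork-class] (or [PriorNetwork-class]), or a node
#'   count.
#' @param nEdges Edge count, when `x` is a node count.
#' @return Numeric density in \[0, 1\].
#' @export
#' @examples
#' networkDensity(22316, 213784257)
setGeneric("networkDensity", function(x, nEdges) {
  standardGeneric("networkDensity")
})

#' @rdname PriorNetwork-class
#' @param x A [PriorNetwork-class].
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname CommunityPartition-class
#' @param x A [CommunityPartition-class].
#' @export
setGeneric("communityAssignment", function(x) {
  standardGeneric("communityAssignment")
})

#' @rdname CommunityPartition-class
#' @export
setGeneric("communitySizes", function(x) standardGeneric("communitySizes"))

#' @rdname CommunityPartition-class
#' @export
setGeneric("nCommunities", function(x) standardGeneric("nCommunities"))

#' @rdname DEProfile-class
#' @param x A [DEProfile-class].
#' @export
setGeneric("exposureId", function(x) standardGeneric("exposureId"))

#' @rdname DEProfile-class
#' @export
setGeneric("systemId", function(x) standardGeneric("systemId"))

#' @rdname DEProfile-class
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

#' FCP scores of a profile
#'
#' Named vector of signed deregulation scores, `logFC * -log(pvalue)`.
#'
#' @param x A [DEProfile-class].
#' @param base Logarithm base for the p-value transform (default 10).
#' @return Named numeric vector over the profiled genes.
#' @export
setGeneric("fcpScores", function(x, base = 10) standardGeneric("fcpScores"))

#' @rdname GeneSelection-class
#' @param x A [GeneSelection-class].
#' @export
setGeneric("upGenes", function(x) standardGeneric("upGenes"))

#' @rdname GeneSelection-class
#' @export
setGeneric("downGenes", function(x) standardGeneric("downGenes"))

#' @rdname GeneSelection-class
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' @rdname LayerDistanceMatrix-class
#' @param x A [LayerDistanceMatrix-class].
#' @export
setGeneric("distanceMatrix", function(x) standardGeneric("distanceMatrix"))

#' @rdname LayerDistanceMatrix-class
#' @export
setGeneric("distanceComponents", function(x) {
  standardGeneric("distanceComponents")
})
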