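#' @import methods
NULL

#' LayerNetwork: one weighted gene-gene similarity view
#'
#' A single prior-knowledge layer: an undirected, weighted gene-gene graph.
#' Edges are stored canonically (`gene_a < gene_b`), weights are strictly
#' positive, self-loops are forbidden and isolated genes are retained in the
#' node set so that layers over the same universe stay comparable.
#'
#' @slot name Layer label (e.g. `"ppi"`, `"pathway"`).
#' @slot nodes Character vector of gene symbols.
#' @slot edges `data.frame` with columns `gene_a`, `gene_b`, `weight`.
#'
#' @export
setClass("LayerNetwork",
  representation(name = "character", nodes = "character",
                 edges = "data.frame"))

setValidity("LayerNetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (!all(c("gene_a", "gene_b", "weight") %in% names(e)))
    msg <- c(msg, "edges need columns gene_a, gene_b, weight")
  else if (nrow(e)) {
    if (any(e$gene_a == e$gene_b)) msg <- c(msg, "self-loop edge present")
    if (any(e$gene_a > e$gene_b))
      msg <- c(msg, "edges must be stored with gene_a < gene_b")
    if (anyDuplicated(paste(e$gene_a, e$gene_b, sep = "\r")))
      msg <- c(msg, "duplicated gene pair in edges")
    if (any(!is.finite(e$weight)) || any(e$weight <= 0))
      msg <- c(msg, "edge weights must be finite and > 0")
    if (!all(c(e$gene_a, e$gene_b) %in% object@nodes))
      msg <- c(msg, "edge genes missing from node set")
  }
  if (anyDuplicated(object@nodes)) msg <- c(msg, "duplicated nodes")
  if (any(grepl("[[:space:]]", object@nodes)) || any(!nzchar(object@nodes)))
    msg <- c(msg, "gene symbols must be non-empty and whitespace-free")
  if (length(msg)) msg else TRUE
})

#' Construct a LayerNetwork
#'
#' @param name Layer label.
#' @param nodes Character vector of gene symbols; defaults to the genes
#'   appearing in `edges`.
#' @param edges `data.frame` with columns `gene_a`, `gene_b`, `weight`;
#'   pairs are canonicalised to `gene_a < gene_b`.
#' @return A [LayerNetwork-class] object.
#' @export
LayerNetwork <- function(name, edges, nodes = NULL) {
  if (nrow(edges)) {
    edges <- .makeEdges(as.character(edges$gene_a),
                        as.character(edges$gene_b), edges$weight)
  } else {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  nodes <- sort(unique(c(nodes, edges$gene_a, edges$gene_b)))
  new("LayerNetwork", name = name, nodes = nodes, edges = edges)
}

#' PriorNetwork: the fused gene similarity network
#'
#' The result of hierarchically merging several [LayerNetwork-class]
#' objects. Weights lie in (0, 1] with the strongest edge at exactly 1;
#' `provenance` records the layer clustering, merge order and scaling
#' constants so the fusion is auditable.
#'
#' @slot provenance List describing the two-stage merge.
#' @export
setClass("PriorNetwork", contains = "LayerNetwork",
  representation(provenance = "list"))

setValidity("PriorNetwork", function(object) {
  w <- object@edges$weight
  if (length(w) && (max(w) > 1 + 1e-9 || abs(max(w) - 1) > 1e-9))
    "fused weights must lie in (0, 1] with max exactly 1" else TRUE
})

#' LayerDistanceMatrix: binary-edge distances between layers
#'
#' Symmetric distance matrix over layers, the equally weighted sum of a
#' Jaccard distance, a simple-matching-coefficient distance and a
#' shared-edge-fraction distance on the layers' binary edge sets, min-max
#' scaled over the off-diagonal into \[0, 1\]. The unscaled component
#' matrices are retained.
#'
#' @slot layerNames Ordered layer labels.
#' @slot D Scaled combined distance matrix (diagonal 0).
#' @slot components Named list of the three unscaled component matrices.
#' @slot universeSize Number of binary edges in the union universe.
#' @export
setClass("LayerDistanceMatrix",
  representation(layerNames = "character", D = "matrix",
                 components = "list", universeSize = "numeric"))

setValidity("LayerDistanceMatrix", function(object) {
  D <- object@D
  msg <- character()
  if (nrow(D) != ncol(D) || nrow(D) != length(object@layerNames))
    msg <- c(msg, "D must be square with one row per layer")
  if (any(abs(D - t(D)) > 1e-12)) msg <- c(msg, "D must be symmetric")
  if (any(diag(D) != 0)) msg <- c(msg, "diagonal of D must be 0")
  if (length(msg)) msg else TRUE
})

#' CommunityPartition: gene-to-community assignment
#'
#' Total, disjoint assignment of every prior-network gene to one community.
#' Community ids are 0-based contiguous integers.
#'
#' @slot assignment Named integer vector, gene -> community id.
#' @export
setClass("CommunityPartition",
  representation(assignment = "integer"))

setValidity("CommunityPartition", function(object) {
  a <- object@assignment
  msg <- character()
  if (is.null(names(a)) || anyDuplicated(names(a)))
    msg <- c(msg, "assignment must be named uniquely by gene")
  if (length(a)) {
    ids <- sort(unique(a))
    if (!identical(ids, seq_len(length(ids)) - 1L))
      msg <- c(msg, "community ids must be 0-based contiguous integers")
  }
  if (length(msg)) msg else TRUE
})

#' DEProfile: differential-expression profile of one exposure
#'
#' Per-gene log fold change and p-value for a single exposure on a single
#' biological system. P-values must lie in (0, 1].
#'
#' @slot exposure Exposure (compound) identifier.
#' @slot system Biological-system (cell line) identifier.
#' @slot table `data.frame` with columns `gene`, `logFC`, `pvalue`.
#' @export
setClass("DEProfile",
  representation(exposure = "character", system = "character",
                 table = "data.frame"))

setValidity("DEProfile", function(object) {
  t <- object@table
  msg <- character()
  if (!all(c("gene", "logFC", "pvalue") %in% names(t)))
    msg <- c(msg, "table needs columns gene, logFC, pvalue")
  else {
    if (anyDuplicated(t$gene)) msg <- c(msg, "one row per gene required")
    if (any(!is.finite(t$logFC))) msg <- c(msg, "logFC must be finite")
    if (any(t$pvalue <= 0 | t$pvalue > 1))
      msg <- c(msg, "p-values must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DEProfile
#'
#' @param exposure,system Identifiers of the exposure and the biological
#'   system.
#' @param gene,logFC,pvalue Equal-length vectors (or a `data.frame` passed
#'   as `gene`) defining one row per gene.
#' @return A [DEProfile-class] object.
#' @export
DEProfile <- function(exposure, system, gene, logFC = NULL, pvalue = NULL) {
  tab <- if (is.data.frame(gene)) gene else
    data.frame(gene = as.character(gene), logFC = logFC, pvalue = pvalue,
               stringsAsFactors = FALSE)
  tab$gene <- as.character(tab$gene)
  rownames(tab) <- NULL
  new("DEProfile", exposure = exposure, system = system,
      table = tab[, c("gene", "logFC", "pvalue")])
}

#' GeneSelection: the most deregulated genes of one exposure
#'
#' Ordered up- and down-regulated gene lists selected from a [DEProfile]
#' restricted to the prior network. `up` is ordered most-positive-first,
#' `down` most-negative-first; the two lists are disjoint.
#'
#' @slot up,down Character vectors of gene symbols.
#' @export
setClass("GeneSelection",
  representation(up = "character", down = "character"))

setValidity("GeneSelection", function(object) {
  if (length(intersect(object@up, object@down)))
    return("up and down lists must be disjoint")
  if (anyDuplicated(object@up) || anyDuplicated(object@down))
    return("duplicated gene in selection")
  TRUE
})
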