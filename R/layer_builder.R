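#' Build a similarity layer from evidence edges
#'
#' Converts raw gene-gene evidence (one row per gene pair per supporting
#' data source) into a weighted similarity layer: the weight of a pair is
#' the number of distinct sources supporting it. Duplicated
#' (gene, gene, source) triples are deduplicated silently; edge identity is
#' the unordered pair.
#'
#' @param edges `data.frame` with columns `gene_a`, `gene_b`, `source`.
#' @param name Layer label.
#' @return A [LayerNetwork-class] with integer source-count weights.
#' @seealso [buildLayerFromAssociations()], [scaleLayerWeights()]
#' @export
#' @examples
#' ev <- data.frame(gene_a = c("g1", "g1", "g2"),
#'                  gene_b = c("g2", "g2", "g3"),
#'                  source = c("S1", "S2", "S1"))
#' networkEdges(buildLayerFromEdges(ev, "ppi"))
buildLayerFromEdges <- function(edges, name) {
  if (!is.data.frame(edges) ||
      !all(c("gene_a", "gene_b", "source") %in% names(edges)))
    stop("'edges' must be a data.frame with columns gene_a, gene_b, source")
  if (nrow(edges) == 0L) stop("no evidence edges supplied")
  a <- as.character(edges$gene_a)
  b <- as.character(edges$gene_b)
  s <- as.character(edges$source)
  loop <- a == b
  if (any(loop))
    stop(sprintf("self-loop edge on gene '%s' rejected", a[which(loop)[1]]))
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi, s, sep = "\r"))
  key <- paste(lo[keep], hi[keep], sep = "\r")
  counts <- rowsum(rep(1, length(key)), key)
  pair <- .splitKey(rownames(counts))
  LayerNetwork(name,
               data.frame(gene_a = pair$a, gene_b = pair$b,
                          weight = as.numeric(counts[, 1]),
                          stringsAsFactors = FALSE))
}

#' Build a similarity layer from gene-entity associations
#'
#' Converts gene-entity association sets (gene-disease, gene-pathway, ...)
#' into a gene-gene similarity layer: two genes are connected iff they
#' share at least one entity, weighted by the number of shared entities.
#' Genes sharing no entity with any other gene stay in the node set as
#' isolated nodes.
#'
#' @param assoc `data.frame` with columns `gene` and `entity`; duplicated
#'   pairs are deduplicated.
#' @param name Layer label.
#' @return A [LayerNetwork-class] with shared-entity-count weights.
#' @export
#' @examples
#' assoc <- data.frame(gene = c("A", "A", "B", "B", "B", "C"),
#'                     entity = c("d1", "d2", "d1", "d2", "d3", "d3"))
#' networkEdges(buildLayerFromAssociations(assoc, "disease"))
buildLayerFromAssociations <- function(assoc, name) {
  if (!is.data.frame(assoc) || !all(c("gene", "entity") %in% names(assoc)))
    stop("'assoc' must be a data.frame with columns gene, entity")
  if (nrow(assoc) == 0L) stop("no associations supplied")
  g <- as.character(assoc$gene)
  e <- as.character(assoc$entity)
  keep <- !duplicated(paste(g, e, sep = "\r"))
  g <- g[keep]
  e <- e[keep]
  keys <- unlist(lapply(split(g, e), function(members) {
    members <- sort(unique(members))
    if (length(members) < 2L) return(character())
    cm <- utils::combn(members, 2L)
    paste(cm[1L, ], cm[2L, ], sep = "\r")
  }), use.names = FALSE)
  if (length(keys)) {
    counts <- rowsum(rep(1, length(keys)), keys)
    pair <- .splitKey(rownames(counts))
    edges <- data.frame(gene_a = pair$a, gene_b = pair$b,
                        weight = as.numeric(counts[, 1]),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  LayerNetwork(name, edges, nodes = unique(g))
}

#' Scale layer weights into (0, 1]
#'
#' Divides every edge weight by the layer maximum, so the strongest edge
#' maps to exactly 1 and weight ratios (hence the weight ordering) are
#' preserved. Applied to every layer before fusion so that layers with
#' different raw weight scales (source counts vs shared-entity counts)
#' become comparable.
#'
#' @param layer A [LayerNetwork-class] with at least one edge.
#' @return The rescaled [LayerNetwork-class]; idempotent.
#' @export
scaleLayerWeights <- function(layer) {
  stopifnot(is(layer, "LayerNetwork"))
  e <- layer@edges
  if (nrow(e) == 0L)
    stop(sprintf("layer '%s' has no edges to scale", layer@name))
  e$weight <- e$weight / max(e$weight)
  initialize(layer, edges = e)
}
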