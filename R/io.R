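#' Read evidence edges from TSV
#'
#' Expects a header and three columns: `gene_a`, `gene_b`, `source`.
#'
#' @param path File path.
#' @return `data.frame` suitable for [buildLayerFromEdges()].
#' @export
readEvidenceEdges <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("gene_a", "gene_b", "source")
  if (!all(need %in% names(df)))
    stop("evidence TSV needs columns gene_a, gene_b, source")
  df[, need]
}

#' Read gene-entity associations from a GMT file
#'
#' One line per entity: `entity_id<TAB>description<TAB>gene1<TAB>gene2...`
#' (parsed with `fgsea::gmtPathways`).
#'
#' @param path File path.
#' @return `data.frame` with columns `gene`, `entity`, suitable for
#'   [buildLayerFromAssociations()].
#' @export
readAssociations <- function(path) {
  sets <- fgsea::gmtPathways(path)
  data.frame(gene = unlist(sets, use.names = FALSE),
             entity = rep(names(sets), lengths(sets)),
             stringsAsFactors = FALSE)
}

#' Write / read a layer network
#'
#' The edge list goes to a 3-column TSV (`gene_a`, `gene_b`, `weight`);
#' name, node list (including isolated nodes) and counts go to a JSON
#' sidecar, so a layer round-trips exactly.
#'
#' @param layer A [LayerNetwork-class].
#' @param path Edge-list TSV path.
#' @param metaPath Sidecar path (default `<path>.json`).
#' @return `writeLayer` returns `path` invisibly; `readLayer` a
#'   [LayerNetwork-class].
#' @export
writeLayer <- function(layer, path, metaPath = paste0(path, ".json")) {
  utils::write.table(networkEdges(layer), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(name = networkName(layer),
                            n_nodes = nNodes(layer),
                            n_edges = nEdges(layer),
                            nodes = networkNodes(layer)),
                       metaPath, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeLayer
#' @param name Layer name override; defaults to the sidecar's, else the
#'   file name.
#' @export
readLayer <- function(path, metaPath = paste0(path, ".json"),
                      name = NULL) {
  edges <- utils::read.delim(path,
                             colClasses = c("character", "character",
                                            "numeric"))
  nodes <- NULL
  if (file.exists(metaPath)) {
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    name <- name %||% meta$name
    nodes <- meta$nodes
  }
  LayerNetwork(name %||% sub("\\.[^.]*$", "", basename(path)), edges,
               nodes = nodes)
}

#' Write / read a differential-expression profile
#'
#' TSV with header `gene`, `logFC`, `pvalue`; exposure and system ids are
#' carried in the file name as `<system>__<exposure>.tsv` unless given
#' explicitly.
#'
#' @param profile A [DEProfile-class].
#' @param path File path.
#' @return `writeDEProfile` returns `path` invisibly; `readDEProfile` a
#'   [DEProfile-class].
#' @export
writeDEProfile <- function(profile, path) {
  utils::write.table(profileTable(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDEProfile
#' @param exposure,system Identifiers; parsed from the file name when
#'   omitted.
#' @export
readDEProfile <- function(path, exposure = NULL, system = NULL) {
  if (is.null(exposure) || is.null(system)) {
    stem <- sub("\\.[^.]*$", "", basename(path))
    parts <- strsplit(stem, "__", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("cannot parse system/exposure from file name; pass them")
    system <- system %||% parts[1L]
    exposure <- exposure %||% parts[2L]
  }
  tab <- utils::read.delim(path,
                           colClasses = c("character", "numeric",
                                          "numeric"))
  DEProfile(exposure, system, tab)
}

#' Write / read a community partition
#'
#' Two-column TSV `gene<TAB>community_id` plus a JSON stats sidecar.
#'
#' @param partition A [CommunityPartition-class].
#' @param path TSV path.
#' @param metaPath Stats sidecar path (default `<path>.json`).
#' @return `writePartition` returns `path` invisibly; `readPartition` a
#'   [CommunityPartition-class].
#' @export
writePartition <- function(partition, path,
                           metaPath = paste0(path, ".json")) {
  a <- communityAssignment(partition)
  utils::write.table(data.frame(gene = names(a), community_id = a),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- partitionStats(partition)
  jsonlite::write_json(s[c("n_communities", "mean_size", "min_size",
                           "max_size")],
                       metaPath, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePartition
#' @export
readPartition <- function(path) {
  df <- utils::read.delim(path, colClasses = c("character", "integer"))
  new("CommunityPartition",
      assignment = stats::setNames(df$community_id, df$gene))
}

#' Write a full synthetic dataset to disk
#'
#' Materialises every input dialect the pipeline consumes: per-layer edge
#' TSVs with sidecars, per-exposure profile TSVs, the annotation table,
#' the expression matrix with its sample sheet, and `truth.json` holding
#' the planted blocks, groups and signatures for recovery scoring.
#'
#' @param cfg A [syntheticConfig()].
#' @param dir Output directory (created if needed).
#' @return The generated objects, invisibly.
#' @export
writeSyntheticDataset <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lay <- generateLayers(cfg)
  exp <- generateExposures(cfg, lay$blocks)
  ann <- generateAnnotations(cfg, exp$groups)
  dir.create(file.path(dir, "layers"), showWarnings = FALSE)
  for (L in lay$layers)
    writeLayer(L, file.path(dir, "layers",
                            paste0(networkName(L), ".tsv")))
  dir.create(file.path(dir, "profiles"), showWarnings = FALSE)
  for (key in names(exp$profiles))
    writeDEProfile(exp$profiles[[key]],
                   file.path(dir, "profiles", paste0(key, ".tsv")))
  utils::write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  x <- SummarizedExperiment::assay(exp$se)
  utils::write.table(data.frame(gene = rownames(x), x,
                                check.names = FALSE),
                     file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(exp$se))
  utils::write.table(data.frame(sample = rownames(cd), cd),
                     file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = cfg$seed,
                            blocks = as.list(lay$blocks),
                            groups = as.list(exp$groups),
                            signatures = exp$signatures),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(layers = lay$layers, blocks = lay$blocks,
                 se = exp$se, profiles = exp$profiles,
                 groups = exp$groups, annotations = ann))
}
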