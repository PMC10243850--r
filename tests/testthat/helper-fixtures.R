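# small in-code fixtures used across test files

# random weighted layer over `nGenes` genes
random_layer <- function(seed, name = "L", nGenes = 20, nEdges = 40,
                         weights = NULL) {
  withr::with_seed(seed, {
    pairs <- t(combn(nGenes, 2))
    pick <- sample(nrow(pairs), min(nEdges, nrow(pairs)))
    genes <- sprintf("g%02d", seq_len(nGenes))
    LayerNetwork(name, data.frame(
      gene_a = genes[pairs[pick, 1]],
      gene_b = genes[pairs[pick, 2]],
      weight = weights %||% runif(length(pick), 0.1, 1)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# layer with an explicit edge list given as "a-b" = weight
edge_layer <- function(name, ...) {
  spec <- c(...)
  parts <- strsplit(names(spec), "-", fixed = TRUE)
  LayerNetwork(name, data.frame(
    gene_a = vapply(parts, `[[`, "", 1),
    gene_b = vapply(parts, `[[`, "", 2),
    weight = unname(spec)))
}

# profile with FCP fully determined by logFC at a fixed p-value
toy_profile <- function(genes, logFC, pvalue = 0.01,
                        exposure = "cpd", system = "sys") {
  DEProfile(exposure, system,
            data.frame(gene = genes, logFC = logFC,
                       pvalue = rep_len(pvalue, length(genes))))
}

toy_partition <- function(...) {
  groups <- list(...)
  asg <- integer()
  for (i in seq_along(groups)) {
    asg[groups[[i]]] <- i - 1L
  }
  new("CommunityPartition", assignment = asg)
}

# default-sized synthetic pipeline run, cached per seed within a session
synthetic_pipeline <- local({
  cache <- list()
  function(seed = 1) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      cfg <- syntheticConfig(seed = seed)
      lay <- generateLayers(cfg)
      prior <- fuseLayers(lay$layers)
      part <- detectCommunities(prior)
      exp <- generateExposures(cfg, lay$blocks)
      cache[[key]] <<- list(cfg = cfg, layers = lay$layers,
                            blocks = lay$blocks, prior = prior,
                            partition = part, se = exp$se,
                            profiles = exp$profiles,
                            groups = exp$groups,
                            signatures = exp$signatures)
    }
    cache[[key]]
  }
})

# measured-data profiles for one system of a pipeline run
system_profiles <- function(run, system, exposures = NULL) {
  exposures <- exposures %||% unique(names(run$groups))
  setNames(lapply(exposures, function(e) {
    differentialProfile(run$se, system, e)
  }), exposures)
}
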