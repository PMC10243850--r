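#' Configuration for the synthetic-data generators
#'
#' Bundles all parameters of the seeded generators with defaults sized so
#' the full pipeline (layer building, fusion, community detection,
#' fingerprinting, benchmarks) runs in well under two minutes on one CPU
#' while preserving the qualitative regime of real knowledge-driven
#' transcriptomics studies: several partially redundant knowledge layers
#' over a few hundred genes organised in small functional modules, tens of
#' exposures in a few planted mechanism groups, replicated expression with
#' biological noise, and a class/structure annotation table.
#'
#' `effectSize / noiseSd` defaults to 4, the signal regime the recovery
#' experiments are specified at. Evidence counts mirror multi-database
#' corroboration: within-module edges draw support from 2-3 sources
#' (`intraWeightProbs`, over counts 1:3), spurious between-module edges
#' are single-source.
#'
#' @param seed Integer master seed; every generator derives its own
#'   stream from it, so generators are order-independent.
#' @param nGenes,nLayers,nBlocks Universe size, number of knowledge
#'   layers, number of planted gene modules.
#' @param intraProb,interProb Per-layer edge probability within / between
#'   blocks.
#' @param intraWeightProbs,interWeightProbs Probabilities of evidence
#'   counts 1:3 for intra- and inter-block edges.
#' @param nSystems,nExposures,nGroups Biological systems, compounds, and
#'   planted compound groups.
#' @param signatureBlocks Gene blocks making up one group's signature.
#' @param effectSize Mean expression shift (log scale) of signature genes
#'   under treatment.
#' @param replicateCount Replicates per control/treated group.
#' @param noiseSd Biological noise standard deviation.
#' @param systemShiftSd,systemShiftFraction Steady-state offsets between
#'   systems: fraction of genes shifted, and the shift scale.
#' @param labelNoise Fraction of class labels resampled at random.
#' @param prefixLength,suffixLength,alphabet Structure-string parameters:
#'   group-mates share a random prefix, so their edit distances are
#'   smaller in expectation.
#' @return A list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(seed = 1, nGenes = 300, nLayers = 6,
                            nBlocks = 20, intraProb = 0.6,
                            interProb = 0.01,
                            intraWeightProbs = c(0, 0.15, 0.85),
                            interWeightProbs = c(1, 0, 0),
                            nSystems = 2, nExposures = 30, nGroups = 3,
                            signatureBlocks = 3, effectSize = 2,
                            replicateCount = 4, noiseSd = 0.5,
                            systemShiftSd = 1,
                            systemShiftFraction = 0.5, labelNoise = 0,
                            prefixLength = 8, suffixLength = 8,
                            alphabet = c("C", "N", "O", "S", "(", ")",
                                         "=", "1", "2", "3")) {
  cfg <- list(seed = as.integer(seed), nGenes = nGenes, nLayers = nLayers,
              nBlocks = nBlocks, intraProb = intraProb,
              interProb = interProb,
              intraWeightProbs = intraWeightProbs,
              interWeightProbs = interWeightProbs, nSystems = nSystems,
              nExposures = nExposures, nGroups = nGroups,
              signatureBlocks = signatureBlocks, effectSize = effectSize,
              replicateCount = replicateCount, noiseSd = noiseSd,
              systemShiftSd = systemShiftSd,
              systemShiftFraction = systemShiftFraction,
              labelNoise = labelNoise, prefixLength = prefixLength,
              suffixLength = suffixLength, alphabet = alphabet)
  with(cfg, {
    stopifnot(nGenes >= 1, nLayers >= 1, nBlocks >= 1, nSystems >= 1,
              nExposures >= 1, nGroups >= 1, replicateCount >= 2,
              effectSize >= 0, noiseSd >= 0,
              intraProb >= 0, intraProb <= 1,
              interProb >= 0, interProb <= 1,
              labelNoise >= 0, labelNoise <= 1,
              length(intraWeightProbs) == 3,
              length(interWeightProbs) == 3)
  })
  structure(cfg, class = "SyntheticConfig")
}

#' Generate planted-block knowledge layers
#'
#' Partitions the gene universe into `nBlocks` equally sized modules and
#' samples, per layer, intra-block edges with probability `intraProb` and
#' inter-block edges with probability `interProb`. Edge weights are
#' integer evidence counts in 1:3 (see [syntheticConfig()]). Layers share
#' the planted blocks but differ in realised edges. An empty layer draw
#' is retried up to 10 times with a warning.
#'
#' @param cfg A [syntheticConfig()].
#' @return List with `layers` (list of [LayerNetwork-class]) and `blocks`
#'   (named integer vector, gene -> block).
#' @export
generateLayers <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  genes <- sprintf("g%04d", seq_len(cfg$nGenes))
  blocks <- stats::setNames(
    sort(rep(seq_len(cfg$nBlocks), length.out = cfg$nGenes)), genes)
  layerNames <- paste0(
    rep(c("ppi", "pathway", "go_bp", "disease", "homolog", "chemical"),
        length.out = cfg$nLayers),
    ifelse(cfg$nLayers > 6, seq_len(cfg$nLayers), ""))
  ij <- t(utils::combn(cfg$nGenes, 2L))
  same <- blocks[ij[, 1L]] == blocks[ij[, 2L]]
  p <- ifelse(same, cfg$intraProb, cfg$interProb)
  layers <- .withSeed(.deriveSeed(cfg$seed, "layers"),
    lapply(seq_len(cfg$nLayers), function(l) {
      for (attempt in seq_len(10L)) {
        keep <- which(stats::runif(nrow(ij)) < p)
        if (length(keep)) break
        warning(sprintf("layer %d drawn empty; regenerating", l))
      }
      if (!length(keep)) stop(sprintf("layer %d stayed empty", l))
      w <- integer(length(keep))
      intra <- same[keep]
      w[intra] <- sample(1:3, sum(intra), TRUE,
                         prob = cfg$intraWeightProbs)
      w[!intra] <- sample(1:3, sum(!intra), TRUE,
                          prob = cfg$interWeightProbs)
      LayerNetwork(layerNames[l],
                   data.frame(gene_a = genes[ij[keep, 1L]],
                              gene_b = genes[ij[keep, 2L]],
                              weight = as.numeric(w),
                              stringsAsFactors = FALSE),
                   nodes = genes)
    }))
  list(layers = layers, blocks = blocks)
}

#' Generate exposures with planted compound groups
#'
#' Assigns each compound group a signature of `signatureBlocks` gene
#' blocks. Treated samples shift signature genes by
#' `sign * effectSize * m`, where the sign is fixed per gene and the
#' multiplier `m ~ U(0.5, 1.5)` is drawn per (system, gene) — so
#' group-mates respond identically within a system while the realised
#' signature pattern differs between systems. All entries carry
#' `N(0, noiseSd)` noise on a log-like additive scale, and a random
#' fraction of genes gets a per-system steady-state offset. Emits both
#' the expression experiment and exact noise-free differential profiles.
#'
#' @param cfg A [syntheticConfig()].
#' @param blocks Named block assignment from [generateLayers()].
#' @return List with `se` (a `SummarizedExperiment`), `profiles` (named
#'   `"system__exposure"` list of noise-free [DEProfile-class]),
#'   `groups` (named integer vector per exposure), `signatures` (list of
#'   gene vectors per group) and `signs`.
#' @export
generateExposures <- function(cfg, blocks) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  genes <- names(blocks)
  nB <- max(blocks)
  if (cfg$nGroups * cfg$signatureBlocks > nB)
    stop("signatures exceed the number of gene blocks")
  systems <- sprintf("system%s", LETTERS[seq_len(cfg$nSystems)])
  exposures <- sprintf("cpd%02d", seq_len(cfg$nExposures))
  groups <- stats::setNames(rep(seq_len(cfg$nGroups),
                                length.out = cfg$nExposures), exposures)
  .withSeed(.deriveSeed(cfg$seed, "exposures"), {
    sigBlocks <- split(sample(nB, cfg$nGroups * cfg$signatureBlocks),
                       rep(seq_len(cfg$nGroups),
                           each = cfg$signatureBlocks))
    signatures <- lapply(sigBlocks,
                         function(bs) genes[blocks %in% bs])
    signs <- stats::setNames(sample(c(-1, 1), length(genes), TRUE),
                             genes)
    mu <- stats::rnorm(length(genes), 7, 1)
    shiftOf <- matrix(0, length(genes), length(systems),
                      dimnames = list(genes, systems))
    mult <- matrix(stats::runif(length(genes) * length(systems),
                                0.5, 1.5),
                   length(genes), length(systems),
                   dimnames = list(genes, systems))
    for (s in systems) {
      hit <- stats::runif(length(genes)) < cfg$systemShiftFraction
      shiftOf[hit, s] <- stats::rnorm(sum(hit), 0, cfg$systemShiftSd)
    }
    nRep <- cfg$replicateCount
    cols <- list()
    vals <- list()
    shifts <- list()      # planted treated shift per (system, exposure)
    for (s in systems) {
      base <- mu + shiftOf[, s]
      for (r in seq_len(nRep)) {
        cols[[length(cols) + 1L]] <-
          data.frame(sample = sprintf("%s_control_r%d", s, r),
                     system = s, exposure = NA_character_,
                     group = "control", stringsAsFactors = FALSE)
        vals[[length(vals) + 1L]] <- base
      }
      for (e in exposures) {
        shift <- stats::setNames(numeric(length(genes)), genes)
        sig <- signatures[[groups[[e]]]]
        shift[sig] <- signs[sig] * cfg$effectSize * mult[sig, s]
        shifts[[paste(s, e, sep = "__")]] <- shift
        for (r in seq_len(nRep)) {
          cols[[length(cols) + 1L]] <-
            data.frame(sample = sprintf("%s_%s_r%d", s, e, r),
                       system = s, exposure = e, group = "treated",
                       stringsAsFactors = FALSE)
          vals[[length(vals) + 1L]] <- base + shift
        }
      }
    }
    cd <- do.call(rbind, cols)
    x <- do.call(cbind, vals) +
      matrix(stats::rnorm(length(genes) * nrow(cd), 0, cfg$noiseSd),
             length(genes), nrow(cd))
    dimnames(x) <- list(genes, cd$sample)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(expr = x),
      colData = S4Vectors::DataFrame(cd[, c("system", "exposure",
                                            "group")],
                                     row.names = cd$sample))
    profiles <- lapply(shifts, function(shift) NULL)
    for (key in names(shifts)) {
      parts <- strsplit(key, "__", fixed = TRUE)[[1L]]
      shift <- shifts[[key]]
      profiles[[key]] <- DEProfile(parts[2L], parts[1L],
        data.frame(gene = genes, logFC = unname(shift),
                   pvalue = ifelse(shift != 0, 1e-4, 1),
                   stringsAsFactors = FALSE))
    }
    list(se = se, profiles = profiles, groups = groups,
         signatures = signatures, signs = signs)
  })
}

#' Generate compound class and structure annotations
#'
#' Class labels reproduce the planted groups (optionally corrupted by
#' `labelNoise`); structure strings share a random per-group prefix
#' followed by a random per-compound suffix, so edit distances between
#' group-mates are smaller in expectation than between non-mates. With
#' `prefixLength = 0` the strings carry no group signal.
#'
#' @param cfg A [syntheticConfig()].
#' @param groups Named group assignment from [generateExposures()].
#' @return `data.frame` with columns `exposure`, `class_label`,
#'   `structure`.
#' @export
generateAnnotations <- function(cfg, groups) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  rstr <- function(len) {
    if (len == 0L) return("")
    paste(sample(cfg$alphabet, len, TRUE), collapse = "")
  }
  .withSeed(.deriveSeed(cfg$seed, "annotations"), {
    labels <- groups
    flip <- stats::runif(length(groups)) < cfg$labelNoise
    labels[flip] <- sample(seq_len(cfg$nGroups), sum(flip), TRUE)
    prefixes <- vapply(seq_len(cfg$nGroups),
                       function(g) rstr(cfg$prefixLength), "")
    data.frame(exposure = names(groups),
               class_label = sprintf("class%02d", labels),
               structure = vapply(seq_along(groups), function(i) {
                 paste0(prefixes[groups[i]], rstr(cfg$suffixLength))
               }, ""),
               stringsAsFactors = FALSE, row.names = NULL)
  })
}
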