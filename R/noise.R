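# build the exposures-by-features matrix for one representation.
# profiles: named list of DEProfile (one system). selections: optional
# named list of gene sets overriding selectDeregulated (used by the
# gene-replacement experiment). For "gsea", permutation seeds are derived
# per (target, reference) only, so p-value noise is shared across
# perturbation levels.
.fingerprintMatrix <- function(profiles, method, partition = NULL,
                               networkGenes = NULL, universe = NULL,
                               nUp = 100, nDown = 100, base = 10,
                               weightExponent = 1, nPerm = 200,
                               seed = NULL, selections = NULL) {
  ids <- names(profiles)
  getSel <- function(id) {
    if (!is.null(selections)) return(.selectionGenes(selections[[id]]))
    selectedGenes(selectDeregulated(profiles[[id]], networkGenes,
                                    nUp, nDown, base = base))
  }
  rows <- switch(method,
    knemap = lapply(ids, function(id) {
      knemapVector(getSel(id), partition)
    }),
    bdg = lapply(ids, function(id) bdgVector(getSel(id), universe)),
    fc = lapply(ids, function(id) fcVector(profiles[[id]], universe,
                                           base = base)),
    gsea = {
      ranked <- lapply(profiles, .fcpRanking, base = base)
      lapply(ids, function(id) {
        set <- getSel(id)
        others <- sort(setdiff(ids, id))
        vapply(stats::setNames(others, others), function(r) {
          s <- if (is.null(seed)) NULL else .deriveSeed(seed, id, r)
          gseaEnrichment(set, ranked[[r]],
                         weightExponent = weightExponent,
                         nPerm = nPerm, seed = s)$pvalue
        }, 0)
      })
    },
    stop(sprintf("unknown method '%s'", method)))
  out <- do.call(rbind, rows)
  rownames(out) <- ids
  out
}

# all (system, exposure) treated combinations of an experiment
.exposureDesign <- function(se) {
  cd <- SummarizedExperiment::colData(se)
  trt <- cd[cd$group == "treated", , drop = FALSE]
  unique(data.frame(system = trt$system, exposure = trt$exposure,
                    stringsAsFactors = FALSE))
}

#' Expression-noise robustness experiment
#'
#' Adds zero-mean Gaussian noise to every expression value, recomputes the
#' differential profiles ([differentialProfile()]) and the per-method
#' exposure vectors at each noise level, and measures each exposure's
#' cosine distance to its noise-free vector. Reported per level are the
#' mean and standard deviation across all exposures (systems pooled), plus
#' the trapezoidal AUC over the level grid per method; the grid is
#' anchored at level 0 with distance exactly 0.
#'
#' One standard-normal draw per expression value is made up front and
#' scaled by each noise level (still `N(0, sigma)` marginally), so the
#' perturbation grows along a fixed direction and curves are comparable
#' across levels rather than re-randomised at each one.
#'
#' @param se Expression `SummarizedExperiment` as in
#'   [differentialProfile()].
#' @param partition A [CommunityPartition-class] over the prior-network
#'   genes.
#' @param sigmas Noise standard deviations (default the
#'   0.01, 0.1, ..., 1 grid).
#' @param methods Subset of `"knemap"`, `"fc"`, `"gsea"`.
#' @param nUp,nDown,base,weightExponent,nPerm Vector-building parameters.
#' @param seed Integer seed governing the noise draw and GSEA
#'   permutations.
#' @return List with `levels`, `mean` and `sd` (level-by-method
#'   matrices) and `auc` (named vector).
#' @export
gaussianNoiseExperiment <- function(se, partition,
                                    sigmas = c(0.01, seq(0.1, 1, 0.1)),
                                    methods = c("knemap", "fc", "gsea"),
                                    nUp = 100, nDown = 100, base = 10,
                                    weightExponent = 1, nPerm = 100,
                                    seed = 1) {
  methods <- match.arg(methods, c("knemap", "fc", "gsea"),
                       several.ok = TRUE)
  sigmas <- sort(sigmas)
  if (any(sigmas <= 0)) stop("noise levels must be positive")
  x <- SummarizedExperiment::assay(se)
  cd <- SummarizedExperiment::colData(se)
  networkGenes <- names(communityAssignment(partition))
  universe <- rownames(x)
  design <- .exposureDesign(se)
  Z <- .withSeed(.deriveSeed(seed, "expression-noise"),
                 matrix(stats::rnorm(length(x)), nrow(x), ncol(x)))
  vectorsAt <- function(noisy) {
    seN <- SummarizedExperiment::SummarizedExperiment(
      assays = list(noisy), colData = cd)
    out <- list()
    for (sys in unique(design$system)) {
      exps <- design$exposure[design$system == sys]
      profs <- stats::setNames(lapply(exps, function(e) {
        differentialProfile(seN, sys, e)
      }), exps)
      out[[sys]] <- lapply(stats::setNames(methods, methods),
        function(m) {
          .fingerprintMatrix(profs, m, partition = partition,
                             networkGenes = networkGenes,
                             universe = universe, nUp = nUp,
                             nDown = nDown, base = base,
                             weightExponent = weightExponent,
                             nPerm = nPerm,
                             seed = .deriveSeed(seed, "gsea", sys))
        })
    }
    out
  }
  baseline <- vectorsAt(x)
  levels <- c(0, sigmas)
  nExp <- nrow(design)
  meanM <- sdM <- matrix(0, length(levels), length(methods),
                         dimnames = list(NULL, methods))
  for (li in seq_along(sigmas)) {
    vecs <- vectorsAt(x + sigmas[li] * Z)
    for (m in methods) {
      d <- unlist(lapply(names(vecs), function(sys) {
        V0 <- baseline[[sys]][[m]]
        V1 <- vecs[[sys]][[m]]
        vapply(rownames(V0),
               function(e) cosineDistance(V0[e, ], V1[e, ]), 0)
      }))
      meanM[li + 1L, m] <- mean(d)
      sdM[li + 1L, m] <- stats::sd(d)
    }
  }
  list(levels = levels, mean = meanM, sd = sdM, n_exposures = nExp,
       auc = apply(meanM, 2L, function(y) .aucTrapezoid(levels, y)))
}

#' Gene-replacement noise experiment
#'
#' Perturbs each exposure's deregulation signature directly: every
#' selected gene is replaced, with probability p, by a randomly drawn
#' gene from the measured universe not already in the selection
#' (replacements are drawn without replacement, so the signature size is
#' conserved even at p = 1). Vectors are rebuilt from the perturbed
#' signatures and compared with the baseline by cosine distance;
#' mean/sd/AUC are reported as in [gaussianNoiseExperiment()].
#'
#' One uniform draw and one replacement gene per selected position are
#' fixed up front and shared across probabilities, so perturbations are
#' nested across the grid.
#'
#' @param profiles Named list of [DEProfile-class] objects for one
#'   system.
#' @param partition A [CommunityPartition-class].
#' @param probs Replacement probabilities (default the 0.01, 0.1, ..., 1
#'   grid).
#' @param methods Subset of `"knemap"`, `"bdg"`, `"gsea"`.
#' @param universe Measured-gene universe replacements are drawn from;
#'   defaults to the partition's genes (so every replacement stays
#'   mappable to a community).
#' @param nUp,nDown,base,weightExponent,nPerm Vector-building parameters.
#' @param seed Integer seed.
#' @return List with `levels`, `mean`, `sd` and `auc`.
#' @export
replacementNoiseExperiment <- function(profiles, partition,
                                       probs = c(0.01, seq(0.1, 1, 0.1)),
                                       methods = c("knemap", "bdg"),
                                       universe = NULL, nUp = 100,
                                       nDown = 100, base = 10,
                                       weightExponent = 1, nPerm = 100,
                                       seed = 1) {
  methods <- match.arg(methods, c("knemap", "bdg", "gsea"),
                       several.ok = TRUE)
  probs <- sort(probs)
  if (any(probs <= 0 | probs > 1))
    stop("replacement probabilities must lie in (0, 1]")
  universe <- universe %||% names(communityAssignment(partition))
  ids <- names(profiles)
  baseSel <- lapply(stats::setNames(ids, ids), function(id) {
    selectedGenes(selectDeregulated(profiles[[id]], universe,
                                    nUp, nDown, base = base))
  })
  draws <- .withSeed(.deriveSeed(seed, "replacement-noise"),
    lapply(ids, function(id) {
      sel <- baseSel[[id]]
      pool <- setdiff(universe, sel)
      if (length(pool) < length(sel))
        stop("universe must be strictly larger than the selection")
      list(u = stats::runif(length(sel)),
           repl = sample(pool, length(sel)))
    }))
  names(draws) <- ids
  build <- function(sels) {
    lapply(stats::setNames(methods, methods), function(m) {
      .fingerprintMatrix(profiles, m, partition = partition,
                         universe = universe, nUp = nUp, nDown = nDown,
                         base = base, weightExponent = weightExponent,
                         nPerm = nPerm,
                         seed = .deriveSeed(seed, "gsea"),
                         selections = sels)
    })
  }
  baseline <- build(baseSel)
  levels <- c(0, probs)
  meanM <- sdM <- matrix(0, length(levels), length(methods),
                         dimnames = list(NULL, methods))
  for (li in seq_along(probs)) {
    sels <- lapply(stats::setNames(ids, ids), function(id) {
      sel <- baseSel[[id]]
      hit <- draws[[id]]$u < probs[li]
      sel[hit] <- draws[[id]]$repl[hit]
      sel
    })
    vecs <- build(sels)
    for (m in methods) {
      d <- vapply(ids, function(e) {
        cosineDistance(baseline[[m]][e, ], vecs[[m]][e, ])
      }, 0)
      meanM[li + 1L, m] <- mean(d)
      sdM[li + 1L, m] <- stats::sd(d)
    }
  }
  list(levels = levels, mean = meanM, sd = sdM,
       auc = apply(meanM, 2L, function(y) .aucTrapezoid(levels, y)))
}

#' Fingerprint stability under steady-state gene subsetting
#'
#' Flags genes as differentially expressed between the control samples of
#' at least one pair of biological systems (Welch test at level `alpha`),
#' then compares community fingerprints computed from the full gene
#' universe with fingerprints restricted to the stable (non-flagged)
#' genes: per system and exposure pair, the difference in cosine distance
#' between the two vector sets. A distribution of differences centred
#' near zero means the representation is robust to steady-state
#' expression differences between systems.
#'
#' @param se Expression `SummarizedExperiment` with >= 2 systems, each
#'   with >= 2 control replicates.
#' @param partition A [CommunityPartition-class].
#' @param alpha Significance level for the control-vs-control test
#'   (default 0.05).
#' @param nUp,nDown,base Selection parameters.
#' @return List with `differences` (stable minus full distance per
#'   exposure pair), `median_difference`, `flagged_fraction` and
#'   `n_stable`.
#' @export
subsetStability <- function(se, partition, alpha = 0.05, nUp = 100,
                            nDown = 100, base = 10) {
  x <- SummarizedExperiment::assay(se)
  cd <- SummarizedExperiment::colData(se)
  systems <- unique(cd$system)
  if (length(systems) < 2L) stop("need at least two systems")
  ctl <- lapply(stats::setNames(systems, systems), function(s) {
    x[, cd$system == s & cd$group == "control", drop = FALSE]
  })
  flagged <- rep(FALSE, nrow(x))
  for (i in seq_len(length(systems) - 1L)) {
    for (j in seq(i + 1L, length(systems))) {
      p <- .welchRows(ctl[[i]], ctl[[j]])$pvalue
      flagged <- flagged | (p < alpha)
    }
  }
  networkGenes <- names(communityAssignment(partition))
  stable <- intersect(networkGenes, rownames(x)[!flagged])
  if (length(stable) == 0L)
    stop("no stable genes between the control samples")
  design <- .exposureDesign(se)
  diffs <- numeric()
  for (sys in unique(design$system)) {
    exps <- design$exposure[design$system == sys]
    if (length(exps) < 2L) next
    vec <- function(genes) {
      t(vapply(exps, function(e) {
        prof <- differentialProfile(se, sys, e)
        knemapVector(selectDeregulated(prof, genes, nUp, nDown,
                                       base = base), partition)
      }, numeric(nCommunities(partition))))
    }
    full <- vec(networkGenes)
    sub <- vec(stable)
    for (i in seq_len(length(exps) - 1L)) {
      for (j in seq(i + 1L, length(exps))) {
        dFull <- cosineDistance(full[i, ], full[j, ])
        dSub <- cosineDistance(sub[i, ], sub[j, ])
        diffs[paste(sys, exps[i], exps[j], sep = ":")] <- dSub - dFull
      }
    }
  }
  list(differences = diffs,
       median_difference = stats::median(diffs),
       flagged_fraction = mean(flagged),
       n_stable = length(stable))
}
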