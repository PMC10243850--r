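---
title: "Methods: knowledge-driven network mapping of transcriptomic profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knowledge-driven network mapping of transcriptomic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knemap)
```

## The problem

Transcriptomic responses to chemical exposures are usually compared gene
by gene: by correlating fold-change vectors, by intersecting lists of
deregulated genes, or by enrichment of one exposure's gene list in
another's ranking. All three inherit the noise of individual gene
measurements and ignore that genes act in groups. This package implements
a network-mapping alternative: genes are first organised into *similarity
communities* using multiple layers of prior knowledge, and each exposure
is then summarised by how its most deregulated genes distribute over
those communities. Two exposures that hit the same functional
neighbourhoods look similar even when the individual genes they perturb
overlap poorly — and a measurement error on one gene barely moves the
fingerprint, because the gene's community carries many others.

## The prior network

Each knowledge source becomes one weighted, undirected gene–gene
similarity layer (`buildLayerFromEdges()`, `buildLayerFromAssociations()`):

* **Edge-type sources** (e.g. protein–protein interactions): the weight
  of a pair is the number of distinct data sources supporting the edge.
* **Association-type sources** (gene–disease, gene–pathway, ...): two
  genes are connected iff they share at least one entity, weighted by the
  shared-entity count. Raw counts are used rather than a size-normalised
  overlap (e.g. Jaccard of the entity sets), because the weight is meant
  to count concordant evidence, and the subsequent rescaling removes
  scale anyway. Genes with only private entities are kept as isolated
  nodes so all layers live on a comparable universe.

Every layer is rescaled into (0, 1] by dividing by its maximum weight
(`scaleLayerWeights()`). Division by the maximum, rather than min–max
scaling, keeps weight ratios intact and avoids mapping the weakest real
edge to exactly 0, which would make it indistinguishable from "no edge".

Fusion is hierarchical and data-driven (`fuseLayers()`). Layers are first
compared on *edge presence only* (`binaryLayerDistance()`): the sum of a
Jaccard distance, a simple-matching-coefficient distance and a
shared-edge-fraction distance, equally weighted, min–max scaled over the
off-diagonal into [0, 1]. Two choices here are deliberately documented
because the construction leaves them open:

* The SMC universe is the union of the binary edges of the layers being
  compared, not all `N(N-1)/2` gene pairs — on sparse layers the all-pairs
  variant is dominated by shared absences and carries almost no signal
  (and is quadratic in the gene count for no benefit). The universe size
  is recorded in the result for auditability.
* The shared-fraction denominator is `min(|E_i|, |E_j|)`, making the
  component a containment measure; with the union it would duplicate the
  Jaccard term. Both alternatives (`mean`, `union`) remain available via
  `sharedDenominator=`.

Ward clustering of this distance matrix (`clusterLayers()`, `hclust`
`"ward.D2"`, the scheme scipy calls `ward`) groups redundant layers; `k`
defaults to 3, matching the regime where interaction-like, annotation-like
and association-like layers separate. Layers inside a cluster are merged
first: each layer's weights are rescaled to a common median (0.5 by
default — the midpoint of the scaled range; only relative weights matter
downstream) and summed over the union of edges (`mergeNetworks()`), then
the cluster networks are rescaled to (0, 1] and merged the same way. The
final weights are again divided by their maximum, consistent with the
per-layer scaling. The fused edge and node sets are exactly the unions of
the inputs, and the result is invariant to layer order within clusters.

## Communities

`detectCommunities()` performs agglomerative clustering on the fused
adjacency: connected pairs sit at distance `1 - weight`, unconnected
pairs at the maximal distance 1 (keeping the matrix fully defined), and
the dendrogram is cut at `distanceThreshold = 0.5`. Average linkage is
the default: the aim is many small, tight communities, which average
linkage delivers on dense weighted graphs without the chaining behaviour
of single linkage (both `complete` and `single` are exposed). Merge
heights are passed through a running maximum before cutting — average
linkage is monotone in exact arithmetic, and the guard only absorbs
floating-point jitter. The dense gene-by-gene matrix is materialised,
which is the right trade-off up to a few thousand genes; the vignette's
fixtures use 300.

## Exposure fingerprints

Per gene the deregulation score is `FCP = logFC * -log10(p)`
(`fcpScore()`); base 10 is conventional for p-value transforms,
switchable to natural log, and irrelevant for every ranking-based step
(it rescales all scores by one constant). Profiles are filtered to the
prior network **before** ranking, then the 100 most positive and 100 most
negative FCP genes are selected (`selectDeregulated()`). Shortage on one
side never borrows from the other — "up" and "down" have biological
meaning — and ties break by `|logFC|`, then symbol, for determinism.

The community fingerprint (`knemapVector()`) is the fraction of the
selected genes falling into each community: a vector over *all*
communities that sums to 1. Three baselines share the identical
selection:

* `bdgVector()` — a 0/1 vector over the measured-gene universe;
* `fcVector()` — the raw FCP values over the common measured genes;
* `gseaVector()` — enrichment p-values of the exposure's selection
  against every other exposure's FCP ranking in the same system.

The preranked GSEA (`gseaEnrichment()`) is a weighted Kolmogorov–Smirnov
running sum: hits increment proportionally to `|FCP|^w` (weight exponent
`w = 1` by default, the classical weighted statistic), misses decrement
by `1/(N - n)`; the enrichment score is the signed maximum deviation, and
the p-value is a two-sided gene-label permutation test with 1000
permutations by default, `(1 + #{|ES*| >= |ES|}) / (1 + nPerm)`, fully
seeded. The permutation scheme and exponent are declared defaults, not
values inherited from any particular external implementation.

`differentialProfile()` is the deliberately simple differential stand-in
used by the resampling experiments: mean difference on log-scale
expression plus a two-sided Welch t-test, p-values floored at 1e-300. It
is not a replacement for a moderated linear-model pipeline on real data.

## Benchmarks

`comparison` utilities mirror the evaluation procedures end to end:
Pearson/cosine similarity matrices (all-zero vectors get distance 0 to
each other and 1 to anything else, so degenerate fingerprints never
propagate `NaN`), Ward compound clustering with cross-system Jaccard
overlap (`clusterOverlap()`, consistent-set threshold 0.5 by default),
class-retrieval curves (`classRetrievalCurve()`; the per-class
denominator excludes the query itself, which cannot retrieve itself),
Levenshtein-based reference pair rankings with average ranks on ties
(`referencePairRanking()`, also accepting descriptor matrices via cosine
distance), rank-agreement curves with absolute rank differences
(`rankAgreement()`; the construction does not fix signed vs absolute
differences — absolute is used), and cross-dataset matching by mean rank
(`crossDatasetMatch()`). All AUCs are plain trapezoids on the stated
grids, unnormalised, since comparisons always share a grid.

The two noise experiments perturb different stages:

* `gaussianNoiseExperiment()` adds `N(0, sigma)` noise to every
  expression value for `sigma` in {0.01, 0.1, ..., 1}, re-runs the
  differential test and the vector construction, and measures each
  exposure's cosine distance to its noise-free vector.
* `replacementNoiseExperiment()` replaces each selected gene with
  probability `p` (same grid) by a random measured gene outside the
  selection, drawn without replacement so the signature size is conserved
  even at `p = 1`.

Both use common random numbers across levels: one standard-normal draw
scaled by `sigma`, one uniform and one replacement assignment per
selected position reused across `p`. Marginally each level still has
exactly the stated distribution, per-level results stay
order-independent, and the perturbation grows along a fixed direction —
so curves measure the effect of the noise level, not re-randomisation
luck between adjacent levels.

`subsetStability()` probes robustness to steady-state differences
between systems: genes differentially expressed between the control
samples of any system pair (Welch, `alpha = 0.05`) are dropped, and
fingerprints from the stable subset are compared with full-universe
fingerprints via per-pair cosine-distance differences.

## The synthetic study fixture

`syntheticConfig()` fixes the conditions everything is validated under:
300 genes in 20 equally sized modules, 6 knowledge layers with
within-module edge probability 0.6 and between-module probability 0.01,
2 systems, 30 exposures in 3 groups whose signatures are 3 modules each,
4 replicates, treatment effect 2 on noise 0.5 (signal-to-noise 4), and
annotations whose structure strings share an 8-character group prefix.
Evidence counts emulate multi-database corroboration: module edges draw
support from {2, 3} sources with probabilities (0.15, 0.85), spurious
between-module edges are single-source. This reflects how curated
knowledge graphs behave — real functional edges recur across sources,
noise edges rarely do — and it is what makes the fused weights bimodal
enough for the 0.5 community cut to trace the modules; with evidence
counts independent of edge type, the division-by-max scaling (driven by
the binomial spread of per-layer membership) pushes typical within-module
weights toward the cut and the modules fragment.

What the generator does *not* emulate: probe-level microarray artifacts,
batch effects, heavy-tailed expression noise, realistic chemistry in the
structure strings, or dependence between knowledge layers beyond the
shared modules. Passing tests therefore demonstrate the machinery and its
qualitative behaviour (noise ordering of the methods, recovery of planted
structure, stability), not quantitative performance on real compendia.

Desk-scale experiment sizes, chosen so the full suite runs in a couple of
minutes: noise experiments use one system and 12 exposures, with 100 GSEA
permutations; the replacement experiment uses 50+50 selections so the
measured universe (300) is three times the signature; the stability
analysis uses 10+10 selections so the selection is well inside the
planted 45-gene signatures — the regime (selection much smaller than the
pool of truly deregulated genes) in which dropped genes are refilled from
the same communities, which is precisely the mechanism the stability
property relies on. At full scale the same ratios hold with room to
spare (200 selected from tens of thousands measured).

## Known limitations

* The community partition of a given network depends on the linkage and
  threshold; published partitions from other implementations will not be
  reproduced bit-for-bit, and no claim of that kind is made.
* The dense distance matrix in `detectCommunities()` is quadratic in the
  gene count; beyond ~10k genes a sparse formulation would be needed.
* `differentialProfile()` assumes log-scale input and per-gene
  independence; use a moderated pipeline upstream for real data and feed
  the resulting tables in as `DEProfile` objects.
* GSEA-based vectors are the noisiest of the four representations (their
  entries are permutation p-values); robustness conclusions about them
  stabilise only after averaging over exposures and simulation seeds.
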