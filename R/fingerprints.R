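#' FCP deregulation score
#'
#' Signed per-gene deregulation score `logFC * -log(pvalue)`. The sign
#' follows the fold change; a p-value of 1 (or a zero fold change) gives a
#' score of 0. P-values below `pFloor` are clamped to keep the transform
#' finite. Base-10 logs are the default; the base rescales scores by a
#' constant and never changes rankings.
#'
#' @param logFC Signed log fold change(s).
#' @param pvalue P-value(s) in (0, 1].
#' @param base Logarithm base (default 10).
#' @param pFloor Lower clamp for p-values (default 1e-300).
#' @return Numeric vector of FCP scores.
#' @export
#' @examples
#' fcpScore(2, 0.01)   # 4
#' fcpScore(-1, 0.1)   # -1
fcpScore <- function(logFC, pvalue, base = 10, pFloor = 1e-300) {
  if (any(!is.finite(pvalue)) || any(pvalue <= 0 | pvalue > 1))
    stop("p-values must lie in (0, 1]")
  logFC * (-log(pmax(pvalue, pFloor), base = base))
}

# genes of a profile ordered by descending FCP, ties by |logFC| descending
# then symbol ascending; returns the named FCP vector in rank order
.fcpRanking <- function(profile, base = 10) {
  tab <- profileTable(profile)
  fcp <- fcpScore(tab$logFC, tab$pvalue, base = base)
  ord <- order(-fcp, -abs(tab$logFC), tab$gene)
  stats::setNames(fcp[ord], tab$gene[ord])
}

#' Rank a profile's genes by FCP
#'
#' @param profile A [DEProfile-class].
#' @param base Logarithm base for [fcpScore()].
#' @return Named numeric vector of FCP scores, most positive first; ties
#'   broken by `|logFC|` descending then gene symbol ascending.
#' @export
fcpRanking <- function(profile, base = 10) .fcpRanking(profile, base)

#' Select the most deregulated network genes
#'
#' Restricts the profile to genes present in the prior network, then takes
#' the `nUp` genes with the most positive FCP and the `nDown` genes with
#' the most negative FCP. Selection never crosses zero: if fewer genes
#' qualify on one side, fewer are taken. Ties are broken by `|logFC|`
#' descending, then gene symbol.
#'
#' @param profile A [DEProfile-class].
#' @param networkGenes Character vector of prior-network genes; the filter
#'   is applied before ranking.
#' @param nUp,nDown Selection sizes (default 100 each, giving the
#'   200-gene deregulation signature).
#' @param base Logarithm base for [fcpScore()].
#' @return A [GeneSelection-class].
#' @export
selectDeregulated <- function(profile, networkGenes, nUp = 100,
                              nDown = 100, base = 10) {
  stopifnot(is(profile, "DEProfile"))
  tab <- profileTable(profile)
  tab <- tab[tab$gene %in% networkGenes, , drop = FALSE]
  if (nrow(tab) == 0L)
    stop("no profiled genes overlap the prior network")
  fcp <- fcpScore(tab$logFC, tab$pvalue, base = base)
  upIdx <- which(fcp > 0)
  upIdx <- upIdx[order(-fcp[upIdx], -abs(tab$logFC[upIdx]),
                       tab$gene[upIdx])]
  dnIdx <- which(fcp < 0)
  dnIdx <- dnIdx[order(fcp[dnIdx], -abs(tab$logFC[dnIdx]),
                       tab$gene[dnIdx])]
  new("GeneSelection",
      up = tab$gene[utils::head(upIdx, nUp)],
      down = tab$gene[utils::head(dnIdx, nDown)])
}

# resolve a GeneSelection or character vector to a gene set
.selectionGenes <- function(selection) {
  if (is(selection, "GeneSelection")) selectedGenes(selection)
  else as.character(selection)
}

#' Community-fraction fingerprint
#'
#' The core exposure representation: for each community of the prior
#' network, the fraction of the selected deregulated genes falling into
#' it. The vector spans all communities (zeros allowed) and sums to 1
#' whenever at least one gene is selected.
#'
#' @param selection A [GeneSelection-class] or character vector of genes;
#'   every gene must be covered by `partition`.
#' @param partition A [CommunityPartition-class].
#' @return Numeric vector of fractions named by 0-based community id.
#' @export
knemapVector <- function(selection, partition) {
  stopifnot(is(partition, "CommunityPartition"))
  genes <- .selectionGenes(selection)
  asg <- communityAssignment(partition)
  K <- nCommunities(partition)
  out <- stats::setNames(numeric(K), as.character(seq_len(K) - 1L))
  if (length(genes) == 0L) return(out)
  miss <- setdiff(genes, names(asg))
  if (length(miss))
    stop(sprintf("selected gene '%s' is not covered by the partition",
                 miss[1]))
  counts <- tabulate(asg[genes] + 1L, nbins = K)
  out[] <- counts / length(genes)
  out
}

#' Binary deregulated-gene vector (BDG baseline)
#'
#' One bit per gene of a fixed measured-gene universe; 1 iff the gene is
#' in the selected deregulation signature.
#'
#' @param selection A [GeneSelection-class] or character vector.
#' @param universe Ordered character vector of measured genes.
#' @return Integer 0/1 vector named by `universe`.
#' @export
bdgVector <- function(selection, universe) {
  genes <- .selectionGenes(selection)
  miss <- setdiff(genes, universe)
  if (length(miss))
    stop(sprintf("selected gene '%s' is outside the universe", miss[1]))
  stats::setNames(as.integer(universe %in% genes), universe)
}

#' FCP value vector (FC baseline)
#'
#' FCP scores of the common measured genes, in a fixed order shared by all
#' exposures.
#'
#' @param profile A [DEProfile-class].
#' @param commonGenes Ordered character vector; every gene must be
#'   profiled.
#' @param base Logarithm base for [fcpScore()].
#' @return Numeric vector named by `commonGenes`.
#' @export
fcVector <- function(profile, commonGenes, base = 10) {
  f <- fcpScores(profile, base = base)
  miss <- setdiff(commonGenes, names(f))
  if (length(miss))
    stop(sprintf("gene '%s' is not profiled", miss[1]))
  f[commonGenes]
}

#' Differential profile from replicate expression data
#'
#' A simple two-sample stand-in for a full linear-model differential
#' pipeline, used by the noise and stability experiments: per gene, the
#' log fold change is the treated-minus-control mean difference (input is
#' assumed on a log-like scale) and the p-value comes from a two-sided
#' Welch t-test. P-values are floored at `pFloor`.
#'
#' @param se A `SummarizedExperiment` whose first assay is a gene-by-sample
#'   matrix and whose `colData` has columns `system`, `exposure` and
#'   `group` (`"control"` / `"treated"`). Controls are shared per system.
#' @param system,exposure Identifiers selecting the treated samples.
#' @param pFloor Lower clamp for p-values.
#' @return A [DEProfile-class].
#' @export
differentialProfile <- function(se, system, exposure, pFloor = 1e-300) {
  cd <- SummarizedExperiment::colData(se)
  x <- SummarizedExperiment::assay(se)
  trt <- which(cd$system == system & cd$group == "treated" &
                 !is.na(cd$exposure) & cd$exposure == exposure)
  ctl <- which(cd$system == system & cd$group == "control")
  if (length(trt) < 2L || length(ctl) < 2L)
    stop("need at least two replicates per group")
  res <- .welchRows(x[, trt, drop = FALSE], x[, ctl, drop = FALSE],
                    pFloor = pFloor)
  DEProfile(exposure, system,
            data.frame(gene = rownames(x), logFC = res$logFC,
                       pvalue = res$pvalue, stringsAsFactors = FALSE))
}

# vectorised two-sided Welch t-test over matrix rows (x1 = treated)
.welchRows <- function(x1, x0, pFloor = 1e-300) {
  n1 <- ncol(x1)
  n0 <- ncol(x0)
  m1 <- rowMeans(x1)
  m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  lfc <- m1 - m0
  p <- rep(1, length(lfc))
  ok <- se2 > 0
  tstat <- lfc[ok] / sqrt(se2[ok])
  df <- se2[ok]^2 /
    ((v1[ok] / n1)^2 / (n1 - 1) + (v0[ok] / n0)^2 / (n0 - 1))
  p[ok] <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # zero within-group variance with a real shift: maximally significant
  p[!ok & lfc != 0] <- pFloor
  list(logFC = lfc, pvalue = pmin(pmax(p, pFloor), 1))
}
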