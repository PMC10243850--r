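# Independent brute-force / DP oracles the implementation is checked
# against. Deliberately naive: nested loops and literal definitions.

# distinct-source count per unordered gene pair
oracle_source_counts <- function(edges) {
  key <- paste(pmin(edges$gene_a, edges$gene_b),
               pmax(edges$gene_a, edges$gene_b))
  out <- list()
  for (k in unique(key)) {
    out[[k]] <- length(unique(edges$source[key == k]))
  }
  out
}

# shared-entity count for every gene pair of an association table
oracle_shared_entities <- function(assoc) {
  genes <- sort(unique(assoc$gene))
  ent <- lapply(genes, function(g) unique(assoc$entity[assoc$gene == g]))
  names(ent) <- genes
  out <- list()
  for (i in seq_along(genes)) {
    for (j in seq_along(genes)) {
      if (i >= j) next
      n <- length(intersect(ent[[i]], ent[[j]]))
      if (n > 0) out[[paste(genes[i], genes[j])]] <- n
    }
  }
  out
}

# Ward agglomeration (squared-distance Lance-Williams recurrence, the
# scheme scipy's "ward" and hclust's "ward.D2" implement), stopped at k
# clusters; returns the membership of each item
oracle_ward_partition <- function(D, k) {
  n <- nrow(D)
  active <- as.list(seq_len(n))
  sizes <- rep(1, n)
  d2 <- D^2
  while (length(active) > k) {
    m <- length(active)
    best <- c(Inf, 0, 0)
    for (i in seq_len(m - 1)) {
      for (j in seq((i + 1), m)) {
        if (d2[i, j] < best[1]) best <- c(d2[i, j], i, j)
      }
    }
    i <- best[2]; j <- best[3]
    ni <- sizes[i]; nj <- sizes[j]
    newd2 <- numeric(m)
    for (l in seq_len(m)) {
      if (l == i || l == j) next
      nl <- sizes[l]
      newd2[l] <- ((ni + nl) * d2[i, l] + (nj + nl) * d2[j, l] -
                     nl * d2[i, j]) / (ni + nj + nl)
    }
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d2[keep, keep, drop = FALSE], newd2[keep]),
                c(newd2[keep], 0))
    active <- c(active[keep], list(c(active[[i]], active[[j]])))
    sizes <- c(sizes[keep], ni + nj)
  }
  member <- integer(n)
  for (c in seq_along(active)) member[active[[c]]] <- c
  member
}

# average-linkage agglomeration, merging while the smallest mean
# inter-cluster distance does not exceed h
oracle_average_cut <- function(D, h) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    m <- length(clusters)
    if (m == 1) break
    best <- c(Inf, 0, 0)
    for (i in seq_len(m - 1)) {
      for (j in seq((i + 1), m)) {
        avg <- mean(D[clusters[[i]], clusters[[j]]])
        if (avg < best[1]) best <- c(avg, i, j)
      }
    }
    if (best[1] > h) break
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
  }
  member <- integer(n)
  for (c in seq_along(clusters)) member[clusters[[c]]] <- c
  member
}

# do two labelings describe the same partition?
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

# textbook dynamic-programming edit distance
oracle_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  d <- matrix(0, length(x) + 1, length(y) + 1)
  d[, 1] <- 0:length(x)
  d[1, ] <- 0:length(y)
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1, d[i + 1, j] + 1,
                             d[i, j] + (x[i] != y[j]))
    }
  }
  d[length(x) + 1, length(y) + 1]
}

# step-by-step walk down the ranked list for the weighted KS running sum
oracle_gsea_walk <- function(stats, hitGenes, exponent = 1) {
  N <- length(stats)
  hits <- names(stats) %in% hitGenes
  n <- sum(hits)
  w <- unname(abs(stats)^exponent)
  NR <- sum(w[hits])
  if (NR == 0) {
    w[] <- 1
    NR <- n
  }
  run <- 0
  best <- 0
  for (i in seq_len(N)) {
    run <- if (hits[i]) run + w[i] / NR else run - 1 / (N - n)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# literal recount of the class-retrieval curve
oracle_retrieval <- function(V, labels, xMax) {
  S <- suppressWarnings(cor(t(V)))
  curve <- numeric(xMax)
  for (cpd in rownames(V)) {
    others <- setdiff(rownames(V), cpd)
    ord <- others[order(-S[cpd, others], others)]
    nClass <- sum(labels[others] == labels[cpd])
    if (nClass == 0) next
    for (x in seq_len(xMax)) {
      curve[x] <- curve[x] +
        sum(labels[ord[seq_len(x)]] == labels[cpd]) / nClass
    }
  }
  curve
}

# literal recount of both rank-agreement curves
oracle_rank_agreement <- function(method, reference, xDiff, xJac) {
  key <- function(d) paste(pmin(d$a, d$b), pmax(d$a, d$b))
  km <- key(method)
  kr <- key(reference)
  rm_ <- setNames(method$rank, km)
  rr <- setNames(reference$rank, kr)
  ordM <- km[order(method$rank, km)]
  ordR <- kr[order(reference$rank, kr)]
  rd <- sapply(xDiff, function(x) {
    top <- ordM[seq_len(x)]
    mean(abs(rm_[top] - rr[top]))
  })
  jc <- sapply(xJac, function(x) {
    a <- ordM[seq_len(x)]
    b <- ordR[seq_len(x)]
    length(intersect(a, b)) / length(union(a, b))
  })
  list(rank_difference = rd, jaccard = jc)
}
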