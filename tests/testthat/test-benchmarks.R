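test_that("pairwise similarity follows the metric definitions", {
  expect_equal(cosineDistance(c(1, 2), c(1, 2)), 0)
  expect_equal(cosineDistance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosineDistance(c(1, 0), c(-1, 0)), 2)
  # all-zero vectors never produce NaN
  expect_equal(cosineDistance(c(0, 0), c(0, 0)), 0)
  expect_equal(cosineDistance(c(0, 0), c(1, 1)), 1)

  V <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, -1, 0))
  D <- pairwiseSimilarity(V, "cosine_distance")
  expect_equal(unname(diag(D)), rep(0, 3))
  expect_equal(D, t(D))
  expect_equal(D["a", "b"], 0)
  expect_true(all(D >= 0 & D <= 2))
  P <- pairwiseSimilarity(V, "pearson")
  expect_equal(P["a", "b"], 1)
  expect_equal(unname(diag(P)), rep(1, 3))
  # matrix path agrees with the scalar definition
  W <- withr::with_seed(2, matrix(rnorm(20), 4, 5,
                                  dimnames = list(paste0("e", 1:4))))
  DW <- pairwiseSimilarity(W, "cosine_distance")
  expect_equal(DW["e1", "e3"], cosineDistance(W[1, ], W[3, ]))
  expect_error(pairwiseSimilarity(W[1, , drop = FALSE]), "two vectors")
})

test_that("compound clustering recovers planted groups", {
  mkVectors <- function(seed, n = 30, k = 3, p = 12, noise = 0.15) {
    withr::with_seed(seed, {
      centers <- matrix(runif(k * p), k, p)
      lab <- rep(seq_len(k), length.out = n)
      V <- centers[lab, ] + matrix(rnorm(n * p, 0, noise), n, p)
      rownames(V) <- sprintf("c%02d", seq_len(n))
      list(V = V, lab = setNames(lab, rownames(V)))
    })
  }
  # strong separation: exact recovery
  strong <- mkVectors(1, noise = 0.02)
  cl <- clusterCompounds(
    pairwiseSimilarity(strong$V, "cosine_distance"), k = 3)
  expect_equal(mclust::adjustedRandIndex(cl, strong$lab), 1)
  # k = n: singletons
  expect_equal(unname(clusterCompounds(
    pairwiseSimilarity(strong$V, "cosine_distance"), k = 30)), 1:30)
  expect_error(clusterCompounds(
    pairwiseSimilarity(strong$V, "cosine_distance"), k = 31), "k must")
  # realistic noise over several seeds
  aris <- vapply(1:10, function(s) {
    d <- mkVectors(s)
    mclust::adjustedRandIndex(
      clusterCompounds(pairwiseSimilarity(d$V, "cosine_distance"), 3),
      d$lab)
  }, 0)
  expect_true(all(aris >= 0.8))
})

test_that("cluster overlap is plain set arithmetic", {
  a <- setNames(c(1, 1, 1, 2, 2, 3, 3, 3), paste0("c", 1:8))
  ov <- clusterOverlap(a, a)
  expect_equal(ov$best_match$jaccard, c(1, 1, 1))
  expect_setequal(ov$consistent, names(a))

  allin <- setNames(rep(1, 8), paste0("c", 1:8))
  singles <- setNames(1:8, paste0("c", 1:8))
  ov2 <- clusterOverlap(allin, singles)
  expect_equal(unname(ov2$jaccard[1, ]), rep(1 / 8, 8))

  # random partitions against a nested-loop recount
  for (seed in 1:3) {
    withr::with_seed(seed, {
      x <- setNames(sample(1:4, 20, TRUE), paste0("c", 1:20))
      y <- setNames(sample(1:3, 20, TRUE), paste0("c", 1:20))
    })
    J <- clusterOverlap(x, y)$jaccard
    for (i in rownames(J)) {
      for (j in colnames(J)) {
        mi <- names(x)[x == as.integer(i)]
        mj <- names(y)[y == as.integer(j)]
        expect_equal(J[i, j], length(intersect(mi, mj)) /
                                length(union(mi, mj)))
      }
    }
  }
  expect_error(clusterOverlap(setNames(1, "a"), setNames(1, "b")),
               "share no")
})

test_that("class retrieval curves count classmates in the top x", {
  # vectors perfectly grouped by class: curve saturates once every
  # classmate is retrieved
  V <- rbind(a1 = c(1, 0, 0), a2 = c(1, 0.01, 0),
             b1 = c(0, 1, 0), b2 = c(0, 1, 0.01))
  lab <- setNames(c("A", "A", "B", "B"), rownames(V))
  rc <- classRetrievalCurve(V, lab)
  expect_equal(unname(rc$scores[1, 1]), 4)    # each query retrieves its mate
  expect_equal(unname(rc$scores[3, 1]), 4)    # and never loses it
  expect_true(all(diff(rc$scores[, 1]) >= 0)) # monotone in x

  # a singleton class contributes nothing
  lab2 <- setNames(c("A", "A", "B", "C"), rownames(V))
  rc2 <- classRetrievalCurve(V, lab2)
  expect_equal(unname(rc2$scores[3, 1]), 2)

  # random data against the nested-loop oracle, multi-method
  for (seed in 1:2) {
    Vr <- withr::with_seed(seed, matrix(
      rnorm(12 * 6), 12, 6, dimnames = list(sprintf("c%02d", 1:12))))
    labr <- setNames(rep(c("x", "y", "z"), 4), rownames(Vr))
    rcr <- classRetrievalCurve(list(m1 = Vr, m2 = Vr^2), labr)
    expect_equal(unname(rcr$scores[, "m1"]),
                 oracle_retrieval(Vr, labr, 11))
    expect_equal(unname(rcr$scores[, "m2"]),
                 oracle_retrieval(Vr^2, labr, 11))
    expect_equal(unname(rcr$auc["m1"]),
                 pracma::trapz(1:11, oracle_retrieval(Vr, labr, 11)))
  }
  expect_error(classRetrievalCurve(V, setNames("A", "a1")), "two label")
})

test_that("edit distances and reference rankings behave", {
  expect_equal(levenshteinDistance("abc", "abc"), 0L)
  expect_equal(levenshteinDistance("abc", "axc"), 1L)
  expect_equal(levenshteinDistance("kitten", "sitting"), 3L)
  strs <- withr::with_seed(7, vapply(1:10, function(i) {
    paste(sample(letters[1:4], sample(3:9, 1), TRUE), collapse = "")
  }, ""))
  for (i in 1:9) {
    expect_equal(levenshteinDistance(strs[i], strs[i + 1]),
                 oracle_levenshtein(strs[i], strs[i + 1]))
  }

  # three strings with forced distances
  r <- referencePairRanking(c(x = "aaaa", y = "aaab", z = "abbb"))
  expect_equal(r$rank[r$a == "x" & r$b == "y"], 1)
  expect_equal(r$rank[r$a == "x" & r$b == "z"], 3)
  # identical strings tie at the average of the tied ranks
  r2 <- referencePairRanking(c(x = "aa", y = "aa", z = "zzzz"))
  expect_equal(r2$rank[r2$a == "x" & r2$b == "y"], 1)
  expect_equal(sort(r2$rank), c(1, 2.5, 2.5))

  # random strings: ranking equals an oracle sort of DP distances
  names(strs) <- sprintf("s%02d", 1:10)
  rr <- referencePairRanking(strs)
  dd <- apply(rr, 1, function(row) {
    oracle_levenshtein(strs[[row["a"]]], strs[[row["b"]]])
  })
  expect_equal(rr$rank, unname(rank(dd, ties.method = "average")))

  # descriptor matrices rank by cosine distance
  M <- withr::with_seed(1, matrix(runif(12), 4, 3,
                                  dimnames = list(letters[1:4])))
  rm_ <- referencePairRanking(M)
  expect_equal(rm_$distance[rm_$a == "a" & rm_$b == "b"],
               cosineDistance(M["a", ], M["b", ]))
})

test_that("rank agreement against a reference ranking", {
  strs <- withr::with_seed(12, setNames(vapply(1:8, function(i) {
    paste(sample(letters[1:5], 8, TRUE), collapse = "")
  }, ""), sprintf("c%02d", 1:8)))
  ref <- referencePairRanking(strs)

  # self-agreement: zero rank difference, full jaccard
  idd <- rankAgreement(ref, ref)
  expect_equal(idd$rank_difference, rep(0, length(idd$x_diff)))
  expect_equal(idd$auc_rank_difference, 0)
  expect_equal(idd$jaccard, rep(1, length(idd$x_jac)))
  expect_equal(idd$auc_jaccard, max(idd$x_jac) - 1)
  # at x = n_pairs even a reversed ranking overlaps fully
  rev_ <- ref
  rev_$rank <- max(ref$rank) + 1 - ref$rank
  expect_equal(tail(rankAgreement(rev_, ref)$jaccard, 1), 1)

  # random method vectors against the nested-loop oracle
  V <- withr::with_seed(3, matrix(rnorm(8 * 10), 8, 10,
                                  dimnames = list(names(strs))))
  meth <- referencePairRanking(V)
  ra <- rankAgreement(meth, ref)
  want <- oracle_rank_agreement(meth, ref, ra$x_diff, ra$x_jac)
  expect_equal(ra$rank_difference, want$rank_difference)
  expect_equal(ra$jaccard, want$jaccard)
  expect_length(ra$top20_rank_difference, 20)
  expect_equal(ra$x_diff, 2:28)   # truncated to the 28 available pairs

  bad <- ref[-1, ]
  expect_error(rankAgreement(bad, ref), "universes differ")
})

test_that("cross-dataset matching aggregates ranks across systems", {
  comm <- paste0("k", 1:4)
  q <- matrix(c(1, 0, 0, 0), 1, 4, dimnames = list("q1", comm))
  candA <- rbind(A = c(1, 0, 0, 0), B = c(0, 1, 0, 0))
  colnames(candA) <- comm
  res <- crossDatasetMatch(list(s1 = q, s2 = q),
                           list(s1 = candA, s2 = candA))
  expect_equal(res$best$best_match, "A")
  expect_equal(res$best$mean_rank, 1)

  # ranks from the two system pairs are averaged
  cand <- rbind(A = c(1, 0, 0, 0), B = c(0.7, 0.7141, 0, 0),
                C = c(0, 1, 0, 0))
  colnames(cand) <- comm
  q2 <- list(s1 = matrix(c(1, 0, 0, 0), 1, 4,
                         dimnames = list("q1", comm)),
             s2 = matrix(c(0.7, 0.7141, 0, 0), 1, 4,
                         dimnames = list("q1", comm)))
  res2 <- crossDatasetMatch(q2, list(s = cand))
  expect_equal(res2$mean_rank["q1", "A"], 2)      # ranks 1 and 3
  expect_equal(res2$best$best_match, "B")         # ranks 2 and 1
  expect_equal(res2$best$mean_rank, 1.5)

  # fingerprints over different community sets are rejected
  qBad <- matrix(1, 1, 3, dimnames = list("q1", paste0("k", 1:3)))
  expect_error(crossDatasetMatch(list(s1 = qBad), list(s1 = candA)),
               "partition mismatch")

  # planted partners are recovered
  hits <- 0
  for (seed in 1:5) {
    withr::with_seed(seed, {
      cands <- matrix(runif(6 * 8), 6, 8,
                      dimnames = list(paste0("d", 1:6),
                                      paste0("k", 1:8)))
      qs <- lapply(1:2, function(s) {
        m <- cands[c(2, 5), ] + matrix(rnorm(16, 0, 0.05), 2, 8)
        rownames(m) <- c("q1", "q2")
        m
      })
    })
    r <- crossDatasetMatch(setNames(qs, c("s1", "s2")),
                           list(sc = cands))
    if (all(r$best$best_match == c("d2", "d5"))) hits <- hits + 1
  }
  expect_gte(hits, 4)
})
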