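test_that("FCP combines fold change and p-value with the right sign", {
  expect_equal(fcpScore(2, 0.01), 4)
  expect_equal(fcpScore(-1, 0.1), -1)
  expect_equal(fcpScore(3, 1), 0)
  expect_equal(fcpScore(0, 0.001), 0)
  expect_error(fcpScore(1, 0), "0, 1")
  expect_error(fcpScore(1, 1.5), "0, 1")
  # p-values below the floor stay finite
  expect_true(is.finite(fcpScore(1, 1e-320)))
  # sign always tracks the fold change
  lfc <- c(-3, -0.1, 0.2, 5)
  expect_equal(sign(fcpScore(lfc, rep(0.03, 4))), sign(lfc))
  # natural-log option rescales without reordering
  f10 <- fcpScore(lfc, c(0.5, 0.01, 0.2, 0.03))
  fe <- fcpScore(lfc, c(0.5, 0.01, 0.2, 0.03), base = exp(1))
  expect_equal(order(f10), order(fe))
})

test_that("selection filters to the network before ranking", {
  genes <- sprintf("g%03d", 1:400)
  lfc <- c(seq(4, 0.02, length.out = 200),
           seq(-0.02, -4, length.out = 200))
  prof <- toy_profile(genes, lfc)
  sel <- selectDeregulated(prof, genes)
  expect_length(upGenes(sel), 100)
  expect_length(downGenes(sel), 100)
  expect_length(selectedGenes(sel), 200)
  # ordered most extreme first
  expect_equal(upGenes(sel)[1], "g001")
  expect_equal(downGenes(sel)[1], "g400")

  # shortage never pads across zero
  short <- toy_profile(paste0("u", 1:50), seq(1, 5, length.out = 50))
  s2 <- selectDeregulated(short, paste0("u", 1:50))
  expect_length(upGenes(s2), 50)
  expect_length(downGenes(s2), 0)

  # the globally strongest gene vanishes when outside the network
  net <- genes[-1]
  s3 <- selectDeregulated(prof, net)
  expect_false("g001" %in% selectedGenes(s3))
  # and equals an independent filter-then-sort
  for (seed in 1:3) {
    p <- withr::with_seed(seed, toy_profile(
      genes, rnorm(400), pvalue = runif(400, 0.001, 1)))
    netG <- withr::with_seed(seed + 50, sample(genes, 250))
    got <- selectDeregulated(p, netG, nUp = 30, nDown = 30)
    tab <- profileTable(p)
    tab <- tab[tab$gene %in% netG, ]
    fcp <- fcpScore(tab$logFC, tab$pvalue)
    ord <- order(-fcp, -abs(tab$logFC), tab$gene)
    expect_equal(upGenes(got), head(tab$gene[ord][fcp[ord] > 0], 30))
    expect_equal(downGenes(got),
                 head(rev(tab$gene[ord])[rev(fcp[ord]) < 0], 30))
  }

  expect_error(selectDeregulated(prof, c("zz1", "zz2")), "overlap")
})

test_that("selection and fingerprint are invariant to FCP rescaling", {
  genes <- sprintf("g%03d", 1:120)
  prof <- withr::with_seed(3, toy_profile(genes, rnorm(120),
                                          pvalue = runif(120, 0.01, 1)))
  scaled <- DEProfile("cpd", "sys", within(profileTable(prof),
                                           logFC <- logFC * 7))
  part <- toy_partition(genes[1:40], genes[41:80], genes[81:120])
  s1 <- selectDeregulated(prof, genes, 25, 25)
  s2 <- selectDeregulated(scaled, genes, 25, 25)
  expect_equal(selectedGenes(s1), selectedGenes(s2))
  expect_equal(knemapVector(s1, part), knemapVector(s2, part))
})

test_that("community fractions normalise over the selection", {
  part <- toy_partition(c("g1", "g2", "g3"), c("g4", "g5"))
  v <- knemapVector(c("g1", "g2", "g4", "g5"), part)
  expect_equal(unname(v), c(0.5, 0.5))
  expect_named(v, c("0", "1"))

  one <- knemapVector(c("g1", "g3"), part)
  expect_equal(unname(one), c(1, 0))

  # spans all communities and sums to one
  part3 <- toy_partition("g1", c("g2", "g3"), c("g4", "g5", "g6"))
  v3 <- knemapVector(c("g2", "g4"), part3)
  expect_length(v3, 3)
  expect_equal(sum(v3), 1, tolerance = 1e-12)
  expect_equal(unname(v3[1]), 0)

  expect_error(knemapVector(c("g1", "zz"), part), "zz")
  expect_equal(sum(knemapVector(character(), part)), 0)
})

test_that("binary and FCP vectors honour their positional contracts", {
  uni <- paste0("g", 1:5)
  b <- bdgVector(c("g2", "g4"), uni)
  expect_equal(unname(b), c(0L, 1L, 0L, 1L, 0L))
  expect_equal(sum(bdgVector(character(), uni)), 0)
  expect_error(bdgVector("g9", uni), "g9")
  # popcount equals selection size
  genes <- sprintf("g%03d", 1:400)
  prof <- toy_profile(genes, c(seq(4, 0.02, length.out = 200),
                               seq(-0.02, -4, length.out = 200)))
  sel <- selectDeregulated(prof, genes)
  expect_equal(sum(bdgVector(sel, genes)), 200)

  fv <- fcVector(toy_profile(c("a", "b", "c"), c(4, -1, 0),
                             pvalue = 0.1), c("a", "b", "c"))
  expect_equal(unname(fv), c(4, -1, 0))
  # permuting the common gene order permutes the vector identically
  fv2 <- fcVector(toy_profile(c("a", "b", "c"), c(4, -1, 0),
                              pvalue = 0.1), c("c", "a", "b"))
  expect_equal(unname(fv2), c(0, 4, -1))
  expect_error(fcVector(toy_profile("a", 1), c("a", "q")), "q")
  # proportional profiles correlate perfectly
  p1 <- toy_profile(letters[1:6], c(1, -2, 3, -1, 2, 0.5))
  p2 <- toy_profile(letters[1:6], c(2, -4, 6, -2, 4, 1))
  expect_equal(cor(fcVector(p1, letters[1:6]),
                   fcVector(p2, letters[1:6])), 1)
})

test_that("welch profiles react to planted shifts and label swaps", {
  genes <- sprintf("g%02d", 1:50)
  mkSE <- function(x1, x0) {
    x <- cbind(x0, x1)
    colnames(x) <- paste0("s", seq_len(ncol(x)))
    rownames(x) <- genes
    SummarizedExperiment::SummarizedExperiment(
      assays = list(x),
      colData = S4Vectors::DataFrame(
        system = "sys",
        exposure = c(rep(NA, ncol(x0)), rep("cpd", ncol(x1))),
        group = c(rep("control", ncol(x0)), rep("treated", ncol(x1))),
        row.names = colnames(x)))
  }
  base <- withr::with_seed(4, matrix(rnorm(50 * 3, 5, 1), 50, 3))

  # identical groups: zero fold change, p-value one
  pr0 <- differentialProfile(mkSE(base, base), "sys", "cpd")
  expect_equal(profileTable(pr0)$logFC, rep(0, 50))
  expect_equal(profileTable(pr0)$pvalue, rep(1, 50))

  # a +2 shift with tiny within-group noise is found
  hits <- 0
  for (seed in 1:10) {
    withr::with_seed(seed, {
      x0 <- matrix(rnorm(50 * 3, 5, 0.05), 50, 3)
      x1 <- x0 + rnorm(50 * 3, 0, 0.05)
      x1[1, ] <- x1[1, ] + 2
    })
    pr <- differentialProfile(mkSE(x1, x0), "sys", "cpd")
    tab <- profileTable(pr)
    if (abs(tab$logFC[1] - 2) < 0.3 && tab$pvalue[1] < 0.05)
      hits <- hits + 1
  }
  expect_gte(hits, 9)

  # swapping group labels negates every fold change
  withr::with_seed(11, {
    x0 <- matrix(rnorm(50 * 4, 5, 1), 50, 4)
    x1 <- matrix(rnorm(50 * 4, 5, 1), 50, 4)
  })
  pa <- differentialProfile(mkSE(x1, x0), "sys", "cpd")
  pb <- differentialProfile(mkSE(x0, x1), "sys", "cpd")
  expect_equal(profileTable(pa)$logFC, -profileTable(pb)$logFC)
  expect_equal(profileTable(pa)$pvalue, profileTable(pb)$pvalue)

  expect_error(differentialProfile(mkSE(x1[, 1, drop = FALSE], x0),
                                   "sys", "cpd"), "two replicates")
})
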