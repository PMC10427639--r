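test_that("rank-sum p-values match full enumeration for small tie-free inputs", {
  expect_equal(wilcoxonRankSum(c(1, 2), c(3, 4)), 1 / 3)
  expect_equal(wilcoxonRankSum(c(1, 2), c(3, 4)),
               enumRankSumP(c(1, 2), c(3, 4)))
  set.seed(20)
  for (i in 1:40) {
    n1 <- sample(1:6, 1)
    n2 <- sample(1:6, 1)
    a <- sample(seq_len(n1 + n2), n1)  # distinct ranks, tie-free
    b <- setdiff(seq_len(n1 + n2), a)
    expect_equal(wilcoxonRankSum(a, b), enumRankSumP(a, b),
                 tolerance = 1e-12)
  }
})

test_that("degenerate rank-sum inputs give p = 1", {
  expect_identical(wilcoxonRankSum(c(2, 2, 2), c(2, 2)), 1)
  expect_equal(wilcoxonRankSum(c(1, 5, 9), c(1, 5, 9)), 1)
  expect_error(wilcoxonRankSum(numeric(0), 1), "length")
  expect_error(wilcoxonRankSum(c(1, NA), c(2, 3)), "finite")
})

test_that("the exact and approximate branches agree near the size boundary", {
  set.seed(30)
  for (i in 1:20) {
    a <- sample(1:12, 6)
    b <- setdiff(1:12, a)
    exact <- wilcoxonRankSum(a, b)  # n1+n2 = 12, tie-free: exact branch
    approx <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("the approximate branch reproduces the standard corrected normal formula", {
  set.seed(31)
  for (i in 1:20) {
    a <- sample(1:8, 20, replace = TRUE)  # ties force the approximation
    b <- sample(1:8, 15, replace = TRUE)
    if (all(c(a, b) == a[1])) next
    expect_equal(wilcoxonRankSum(a, b),
                 suppressWarnings(
                   stats::wilcox.test(a, b, exact = FALSE,
                                      correct = TRUE)$p.value),
                 tolerance = 1e-12)
  }
})

test_that("bonferroni multiplies by the family size and clips at 1", {
  expect_equal(bonferroni(0.01, m = 8), 0.08)
  expect_equal(bonferroni(0.5, m = 8), 1)
  expect_equal(bonferroni(c(0.2, 0.4), m = 2), c(0.4, 0.8))
  expect_equal(bonferroni(0.3, m = 1), 0.3)
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "family size")
})

test_that("per-cell RNA content sums the right chromosome classes", {
  m <- matrix(c(3,   # X gene
                4,   # 2L gene
                1,   # Y gene
                7),  # MT gene (excluded from the three class sums)
              ncol = 1)
  sce <- makeSCE(m, arms = c("X", "2L", "Y", "MT"))
  cl <- ClusterAssignment(stats::setNames(1L, colnames(sce)), k = 1L)
  cc <- rnaContentPerCell(sce, geneAnnotation(sce), cl)
  expect_identical(as.numeric(cc$umi_autosome), 4)
  expect_identical(as.numeric(cc$umi_X), 3)
  expect_identical(as.numeric(cc$umi_Y), 1)
  expect_identical(as.numeric(cc$umi_MT), 7)
})

test_that("content sums conserve the class totals of the matrix", {
  sce <- simulateGermline(SimulationConfig(seed = 17L,
                                           clusterSizes = c(25L, 25L)))
  ann <- geneAnnotation(sce)
  cc <- rnaContentPerCell(sce, ann, trueClusters(sce))
  m <- SummarizedExperiment::assay(sce)
  for (k in c("autosome", "X", "Y", "MT")) {
    expect_equal(sum(cc[[paste0("umi_", k)]]),
                 sum(m[ann$class == k, ]))
  }
  # a cell with counts only on 2R genes contributes nothing to X or Y
  only2R <- makeSCE(matrix(c(5, 0), ncol = 1), arms = c("2R", "X"))
  cl1 <- ClusterAssignment(stats::setNames(1L, colnames(only2R)), k = 1L)
  cc1 <- rnaContentPerCell(only2R, geneAnnotation(only2R), cl1)
  expect_identical(as.numeric(cc1$umi_X), 0)
  expect_identical(as.numeric(cc1$umi_Y), 0)
})

test_that("consecutive-cluster content tests use exact rank-sums and Bonferroni", {
  content <- S4Vectors::DataFrame(
    barcode = sprintf("c%d", 1:6),
    cluster = rep(1:2, each = 3),
    umi_autosome = c(5, 6, 7, 50, 60, 70),
    umi_X = c(5, 6, 7, 5, 6, 7),
    umi_Y = c(0, 1, 2, 0, 1, 2))
  res <- compareContentConsecutive(content, stage_order = 1:2)
  expect_identical(nrow(res), 3L)  # (k-1) pairs x 3 classes
  auto <- res[res$class == "autosome", ]
  expect_equal(auto$p, 2 / choose(6, 3))  # exact enumeration, n = 3,3
  expect_identical(as.integer(auto$direction), 1L)
  expect_equal(auto$p_adj, min(1, 3 * auto$p))
  x <- res[res$class == "X", ]
  expect_equal(x$p, 1)  # identical distributions
  tiny <- content[c(1, 4:6), ]
  expect_message(res2 <- compareContentConsecutive(tiny, 1:2), "< 2 cells")
  expect_true(is.na(res2$p[res2$class == "autosome"]))
})

test_that("per-cluster gene counts are summed and log2(x+1)-transformed exactly", {
  m <- matrix(c(3, 4,   # gene 1: cluster sums 7 -> log2 8 = 3
                0, 0,   # gene 2: 0 -> 0
                1, 0),  # gene 3: 1 -> 1
              nrow = 3, byrow = TRUE)
  sce <- makeSCE(m)
  cl <- ClusterAssignment(stats::setNames(c(1L, 1L), colnames(sce)), k = 1L)
  glc <- geneClusterLogCounts(sce, cl)
  expect_identical(unname(glc@raw[, 1]), c(7, 0, 1))
  expect_identical(unname(glc@log2[, 1]), c(3, 0, 1))
})

test_that("the X/A ratio statistic reproduces hand medians and exact p-values", {
  # X gene log2 values (1,2,3), autosomal (4,5,6): tie-free exact branch
  m <- matrix(c(1, 3, 7, 15, 31, 63), ncol = 1)
  sce <- makeSCE(m, arms = c("X", "X", "X", "2R", "3L", "2L"))
  cl <- ClusterAssignment(stats::setNames(1L, colnames(sce)), k = 1L)
  glc <- geneClusterLogCounts(sce, cl)
  rr <- xaRatioPerCluster(glc, geneAnnotation(sce), "X")
  expect_equal(rr$median_class, 2)
  expect_equal(rr$median_A, 5)
  expect_equal(rr$ratio, 2^(2 - 5))
  expect_equal(rr$p, enumRankSumP(c(1, 2, 3), c(4, 5, 6)))

  # hand medians with ties: X (1,2,3) vs A (2,3,4) -> ratio 0.5
  m2 <- matrix(c(1, 3, 7, 3, 7, 15), ncol = 1)
  sce2 <- makeSCE(m2, arms = c("X", "X", "X", "2R", "3L", "2L"))
  glc2 <- geneClusterLogCounts(sce2, ClusterAssignment(
    stats::setNames(1L, colnames(sce2)), k = 1L))
  rr2 <- xaRatioPerCluster(glc2, geneAnnotation(sce2), "X")
  expect_equal(rr2$median_class, 2)
  expect_equal(rr2$median_A, 3)
  expect_equal(rr2$ratio, 0.5)
  # identical distributions: ratio exactly 1, p exactly 1
  m3 <- matrix(c(1, 3, 7, 1, 3, 7), ncol = 1)
  sce3 <- makeSCE(m3, arms = c("X", "X", "X", "2R", "3L", "2L"))
  glc3 <- geneClusterLogCounts(sce3, ClusterAssignment(
    stats::setNames(1L, colnames(sce3)), k = 1L))
  rr3 <- xaRatioPerCluster(glc3, geneAnnotation(sce3), "X")
  expect_equal(rr3$ratio, 1)
  expect_equal(rr3$p, 1)
  expect_identical(rr3$regime, "dosage_compensated")
})

test_that("the ratio is invariant to a common depth factor at high counts", {
  set.seed(40)
  raw <- matrix(rpois(3000, lambda = 500), ncol = 1)
  arms <- c(rep("X", 500), rep("2R", 2500))
  raw[1:500] <- rpois(500, lambda = 250)
  sce <- makeSCE(raw, arms = arms)
  cl <- ClusterAssignment(stats::setNames(1L, colnames(sce)), k = 1L)
  r1 <- xaRatioPerCluster(geneClusterLogCounts(sce, cl),
                          geneAnnotation(sce), "X")$ratio
  sce4 <- makeSCE(raw * 4, arms = arms)
  r4 <- xaRatioPerCluster(geneClusterLogCounts(sce4, cl),
                          geneAnnotation(sce4), "X")$ratio
  expect_lt(abs(r4 / r1 - 1), 0.01)
})

test_that("regime classification follows the ratio/significance rule", {
  # the two anchor regimes: significant 1.113 -> overexpression,
  # significant 0.488 -> no compensation; non-significant 1.0 -> compensated
  expect_identical(classifyRegime(1.113, 0.002), "overexpression")
  expect_identical(classifyRegime(0.488, 2.1e-71), "no_compensation")
  expect_identical(classifyRegime(1.0, 1.0), "dosage_compensated")
  expect_identical(classifyRegime(0.2, 1e-10), "silenced")
  expect_identical(classifyRegime(0.8, 1e-10), "indeterminate")
  expect_identical(classifyRegime(0.4, 1e-10), "no_compensation")  # band edge
  expect_identical(classifyRegime(0.39, 1e-10), "silenced")
  expect_identical(
    classifyRegime(c(1.113, 0.488), c(0.002, 1e-5)),
    c("overexpression", "no_compensation"))
  # configurable thresholds
  expect_identical(classifyRegime(0.7, 1e-5, bandNoDc = c(0.6, 0.8)),
                   "no_compensation")
})
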