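mkDE <- function(cluster, gene_id, log2fc, p, p_adj,
                 cutoff = 1, alpha = 0.05) {
  df <- S4Vectors::DataFrame(cluster = cluster, gene_id = gene_id,
                             log2fc = log2fc, p = p, p_adj = p_adj,
                             enriched = log2fc > cutoff & p_adj < alpha)
  S4Vectors::metadata(df) <- list(log2fc_cutoff = cutoff, alpha = alpha)
  methods::new("DEResult", df)
}

handDE <- function() {
  # 4 cells (2 per cluster), 2 genes, equal depths so normalisation is the
  # identity and every expected value is hand-computable; values are
  # tie-free within each gene so the exact rank-sum branch applies
  m <- matrix(c(4, 6, 1, 2,
                2, 0, 5, 4), nrow = 2, byrow = TRUE)
  sce <- makeSCE(m, arms = c("2R", "X"))
  cl <- ClusterAssignment(stats::setNames(c(1L, 1L, 2L, 2L), colnames(sce)),
                          k = 2L)
  list(sce = sce, cl = cl, m = m)
}

test_that("cluster-vs-rest log2 fold changes and p-values match hand computation", {
  h <- handDE()
  de <- globallyDistinguishingDE(h$sce, h$cl)
  eps <- 1 / 6  # all depths are 6, so the median depth is 6
  g1c1 <- de[de$cluster == 1 & de$gene_id == "g001", ]
  expect_equal(unname(g1c1$log2fc), log2((5 + eps) / (1.5 + eps)))
  expect_equal(unname(g1c1$p), enumRankSumP(c(4, 6), c(1, 2)))
  expect_equal(unname(g1c1$p), 1 / 3)  # exact: 2 of the 6 rank splits
  g2c1 <- de[de$cluster == 1 & de$gene_id == "g002", ]
  expect_equal(unname(g2c1$log2fc), log2((1 + eps) / (4.5 + eps)))
  expect_equal(unname(g2c1$p), enumRankSumP(c(2, 0), c(5, 4)))
  # antisymmetry with two equal-size clusters and a common pseudocount
  g1c2 <- de[de$cluster == 2 & de$gene_id == "g001", ]
  expect_equal(unname(g1c2$log2fc), -unname(g1c1$log2fc))
})

test_that("an identically distributed gene is never enriched", {
  m <- rbind(rep(c(3, 5), 4), rep(2, 8))
  sce <- makeSCE(m)
  cl <- ClusterAssignment(stats::setNames(rep(1:2, each = 4), colnames(sce)),
                          k = 2L)
  de <- globallyDistinguishingDE(sce, cl)
  expect_true(all(abs(de$log2fc) < 0.2))
  expect_false(any(de$enriched))
})

test_that("the enrichment flag follows the Log2FC > 1 and adjusted p < 0.05 rule", {
  cfg <- SimulationConfig(
    seed = 14L, clusterSizes = c(60L, 60L),
    markerSpec = data.frame(gene = 1:5, cluster = 1L, fold = 20))
  sce <- simulateGermline(cfg)
  sce <- filterGenesExpressed(sce)
  de <- globallyDistinguishingDE(sce, trueClusters(sce))
  expect_identical(de$enriched, de$log2fc > 1 & de$p_adj < 0.05)
  markers <- de[de$cluster == 1 & de$gene_id %in% sprintf("G%05d", 1:5), ]
  expect_true(all(markers$enriched))
  expect_true(all(de$p_adj >= de$p - 1e-12))
})

test_that("the vectorised rank-sum path equals the per-gene statistic", {
  set.seed(5)
  m <- matrix(rpois(40 * 30, 2), nrow = 40)
  sce <- makeSCE(m)
  lab <- stats::setNames(rep(1:3, each = 10), colnames(sce))
  de <- globallyDistinguishingDE(sce, ClusterAssignment(lab, k = 3))
  depth <- colSums(m)
  xm <- sweep(m, 2, stats::median(depth) / depth, `*`)
  for (l in 1:3) {
    for (g in sample(40, 10)) {
      expect_equal(
        unname(de$p[de$cluster == l & de$gene_id == rownames(sce)[g]]),
        wilcoxonRankSum(xm[g, lab == l], xm[g, lab != l]),
        tolerance = 1e-12)
    }
  }
})

test_that("Benjamini-Hochberg matches the hand step-up and stays monotone", {
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjaminiHochberg(0.2), 0.2)
  expect_equal(benjaminiHochberg(rep(0.04, 5)), rep(0.04, 5))
  set.seed(1)
  p <- sort(runif(50))
  adj <- benjaminiHochberg(p)
  expect_true(all(diff(adj) >= -1e-12))
  expect_true(all(adj <= 1))
  expect_error(benjaminiHochberg(c(0.1, NA)), "NA")
  expect_error(benjaminiHochberg(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("the enrichment partition is an exact partition of enriched genes", {
  de <- mkDE(cluster = c(1L, 1L, 2L, 2L, 1L),
             gene_id = c("a", "b", "b", "c", "d"),
             log2fc = c(2, 2, 2, 2, 0.2),
             p = rep(0.001, 5), p_adj = rep(0.004, 5))
  part <- enrichmentPartition(de)
  expect_identical(as.integer(part[["1"]]), 1L)
  expect_identical(as.integer(part[["1+2"]]), 1L)
  expect_identical(as.integer(part[["2"]]), 1L)
  expect_identical(sum(part), length(unique(c("a", "b", "c"))))
  none <- mkDE(cluster = 1L, gene_id = "a", log2fc = 0, p = 0.5, p_adj = 0.5)
  expect_length(enrichmentPartition(none), 0L)
})

test_that("the chromosome breakdown conserves per-cluster enriched counts", {
  cfg <- SimulationConfig(
    seed = 15L, clusterSizes = c(50L, 50L),
    markerSpec = data.frame(gene = c(1:4, 1001:1003),
                            cluster = c(1L, 1L, 1L, 1L, 2L, 2L, 2L),
                            fold = 20))
  sce <- filterGenesExpressed(simulateGermline(cfg))
  de <- globallyDistinguishingDE(sce, trueClusters(sce))
  tab <- enrichmentByChromosome(de, geneAnnotation(sce))
  perCluster <- table(de$cluster[de$enriched])
  for (cl in rownames(tab)) {
    expect_identical(sum(tab[cl, ]), as.integer(perCluster[[cl]]))
  }
})

test_that("marker scoring annotates clusters and breaks ties by earlier stage", {
  de <- mkDE(cluster = c(1L, 1L, 1L, 2L),
             gene_id = c("mA1", "mA2", "mB1", "mB1"),
             log2fc = c(3, 1.5, 2, 0.5),
             p = rep(1e-4, 4), p_adj = rep(4e-4, 4))
  markers <- data.frame(gene_id = c("mA1", "mA2", "mB1"),
                        cell_type = c("typeA", "typeA", "typeB"),
                        stage_rank = c(1, 1, 2))
  ann <- annotateClusters(de, markers)
  expect_identical(ann$cell_type[ann$cluster == 1], "typeA")  # 4.5 > 2
  expect_identical(ann$cell_type[ann$cluster == 2], "unassigned")
  # tie: equal scores go to the earlier stage
  tie <- mkDE(cluster = c(1L, 1L), gene_id = c("mA1", "mB1"),
              log2fc = c(2, 2), p = rep(1e-4, 2), p_adj = rep(4e-4, 2))
  annTie <- suppressWarnings(annotateClusters(tie, markers))
  expect_identical(annTie$cell_type[annTie$cluster == 1], "typeA")
  expect_warning(annotateClusters(de, rbind(markers,
    data.frame(gene_id = "absent", cell_type = "typeC", stage_rank = 3))),
    "absent")
})

test_that("hypergeometric over-representation matches closed-form combinatorics", {
  universe <- paste0("u", 1:10)
  query <- universe[1:4]
  res <- hypergeomOverrepresentation(
    query,
    categories = list(hit = universe[1:5], miss = universe[6:10],
                      self = query),
    universe = universe)
  # N=10, K=5, n=4, k=4: p = C(5,4)C(5,0)/C(10,4) = 5/210
  expect_equal(res$p[res$term == "hit"], 5 / 210)
  expect_equal(res$p[res$term == "self"],
               choose(4, 4) * choose(6, 0) / choose(10, 4))
  expect_equal(res$p[res$term == "miss"], 1)
  expect_true(all(res$p_adj >= res$p))
  expect_error(hypergeomOverrepresentation("x", list(a = "x"), character()),
               "empty universe")
  expect_error(hypergeomOverrepresentation("zz", list(a = "u1"), universe),
               "subset")
})
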