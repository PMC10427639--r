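#' Cluster-versus-rest ("globally distinguishing") differential expression
#'
#' For each cluster c and gene g: `log2fc = log2((mean normalised count in
#' c + eps) / (mean in all other cells + eps))` with the pseudocount
#' `eps = 1 / median(cell depth)` (one would-be count at typical depth, so
#' zero-mean groups cannot produce infinite fold changes), and a two-sided
#' Wilcoxon rank-sum p-value on the normalised counts of c versus the
#' rest. P-values are Benjamini-Hochberg adjusted within each cluster
#' (`adjust = "per_cluster"`, the usual convention) or across all
#' (cluster, gene) pairs (`"global"`). A gene is flagged `enriched` in a
#' cluster when `log2fc > 1` and `p_adj < 0.05`.
#'
#' @param sce a filtered `SingleCellExperiment` with a `counts` assay
#'   (cells are depth-normalised to the median total internally).
#' @param clusters a [ClusterAssignment-class] with >= 2 clusters covering
#'   every cell; empty clusters are an error.
#' @param log2fcCutoff,alpha the enrichment rule thresholds (defaults 1
#'   and 0.05).
#' @param adjust BH family: `"per_cluster"` (default) or `"global"`.
#' @return a [DEResult-class] with one row per (cluster, gene).
#' @export
globallyDistinguishingDE <- function(sce, clusters, log2fcCutoff = 1,
                                     alpha = 0.05,
                                     adjust = c("per_cluster", "global")) {
  adjust <- match.arg(adjust)
  lab <- clusterLabels(clusters)[colnames(sce)]
  if (any(is.na(lab))) stop("some cells have no cluster label")
  present <- levels(lab)[tabulate(lab, nbins = nlevels(lab)) > 0]
  if (length(present) < 2L) stop("need >= 2 non-empty clusters")
  if (length(present) < nlevels(lab)) stop("empty cluster(s) in assignment")
  m <- .counts(sce)
  depth <- Matrix::colSums(m)
  if (any(depth == 0)) stop("zero-total cell(s); filter cells first")
  tgt <- stats::median(depth)
  eps <- 1 / tgt
  # linear depth-normalised counts: fold changes live on this scale; the
  # rank-sum p is invariant to the (monotone) log transform
  norm <- m %*% Matrix::Diagonal(x = tgt / depth)
  dimnames(norm) <- dimnames(m)
  pmat <- .rankSumByCluster(norm, lab)
  res <- lapply(levels(lab), function(l) {
    inC <- lab == l
    mc <- Matrix::rowMeans(norm[, inC, drop = FALSE])
    mr <- Matrix::rowMeans(norm[, !inC, drop = FALSE])
    S4Vectors::DataFrame(cluster = as.integer(l), gene_id = rownames(norm),
                         log2fc = as.numeric(log2((mc + eps) / (mr + eps))),
                         p = pmat[, l])
  })
  out <- do.call(rbind, res)
  out$p_adj <- if (adjust == "per_cluster") {
    unlist(lapply(split(out$p, out$cluster), benjaminiHochberg),
           use.names = FALSE)
  } else {
    benjaminiHochberg(out$p)
  }
  out$enriched <- out$log2fc > log2fcCutoff & out$p_adj < alpha
  metadata(out) <- list(log2fc_cutoff = log2fcCutoff, alpha = alpha,
                        eps = eps, adjust = adjust)
  methods::new("DEResult", out)
}

# Two-sided rank-sum p of every gene (row) for each cluster-vs-rest split.
# With <= 12 cells this defers to wilcoxonRankSum per gene so the exact
# branch applies; with more cells the test is the approximate branch for
# every gene regardless of ties, so it is computed vectorised: ranks (and
# the tie correction) once per gene, rank sums per cluster by one matrix
# product. The two paths implement the identical statistic.
#' @keywords internal
.rankSumByCluster <- function(norm, lab) {
  nCells <- ncol(norm)
  k <- nlevels(lab)
  genes <- nrow(norm)
  pmat <- matrix(NA_real_, genes, k, dimnames = list(rownames(norm),
                                                     levels(lab)))
  if (nCells <= 12L) {
    xm <- as.matrix(norm)
    for (l in levels(lab)) {
      inC <- lab == l
      pmat[, l] <- vapply(seq_len(genes), function(g) {
        wilcoxonRankSum(xm[g, inC], xm[g, !inC])
      }, numeric(1))
    }
    return(pmat)
  }
  ind <- vapply(levels(lab), function(l) as.numeric(lab == l),
                numeric(nCells))
  n1 <- colSums(ind)
  block <- 2000L
  for (start in seq(1L, genes, by = block)) {
    rows <- start:min(start + block - 1L, genes)
    xb <- as.matrix(norm[rows, , drop = FALSE])
    rb <- matrix(0, length(rows), nCells)
    tie <- numeric(length(rows))
    for (i in seq_along(rows)) {
      v <- xb[i, ]
      rb[i, ] <- rank(v)
      len <- rle(sort(v))$lengths
      tie[i] <- sum(len^3 - len)
    }
    rsum <- rb %*% ind
    for (j in seq_len(k)) {
      n2 <- nCells - n1[j]
      u <- rsum[, j] - n1[j] * (n1[j] + 1) / 2
      sigma <- sqrt(n1[j] * n2 / 12 *
                      (nCells + 1 - tie / (nCells * (nCells - 1))))
      d <- u - n1[j] * n2 / 2
      z <- ifelse(sigma > 0, (d - sign(d) * 0.5) / sigma, 0)
      pmat[rows, j] <- pmin(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  pmat
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric p-values in \[0, 1\]; NaN/NA are rejected.
#' @return adjusted p-values (monotone, clipped at 1), via
#'   [stats::p.adjust()].
#' @export
benjaminiHochberg <- function(p) {
  if (any(is.na(p))) stop("p-values must not be NA/NaN")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Partition of enriched genes by the exact set of clusters
#'
#' Every enriched gene is assigned to the exact subset of clusters in
#' which it is enriched (the quantity an UpSet plot displays); the subset
#' counts partition the enriched-gene universe, so they sum to the number
#' of distinct enriched genes.
#'
#' @param de a [DEResult-class].
#' @return named integer vector; names are cluster subsets like `"1"`,
#'   `"2+5"`, sorted by decreasing count.
#' @export
enrichmentPartition <- function(de) {
  hits <- de[de$enriched, , drop = FALSE]
  if (!nrow(hits)) return(stats::setNames(integer(0), character(0)))
  key <- vapply(split(hits$cluster, hits$gene_id),
                function(cl) paste(sort(unique(cl)), collapse = "+"),
                character(1))
  sort(table(key), decreasing = TRUE)
}

#' Cross-tabulation of enriched genes by cluster and chromosome arm
#'
#' @param de a [DEResult-class].
#' @param annotation data.frame with `gene_id` and `arm`.
#' @return integer table, clusters x arms (empty when nothing is enriched).
#' @export
enrichmentByChromosome <- function(de, annotation) {
  hits <- de[de$enriched, , drop = FALSE]
  arm <- annotation$arm[match(hits$gene_id, annotation$gene_id)]
  table(cluster = hits$cluster, arm = arm)
}

#' Marker-based cell-type annotation of clusters
#'
#' Scores each (cluster, cell type) as the sum of `max(log2fc, 0)` over
#' that type's marker genes that are *enriched* in the cluster; each
#' cluster receives the best-scoring type, ties broken toward the earlier
#' developmental stage. Clusters with score 0 are `"unassigned"`. Marker
#' genes absent from the DE table are skipped with a warning.
#'
#' @param de a [DEResult-class].
#' @param markers data.frame with columns `gene_id`, `cell_type`,
#'   `stage_rank` (a total preorder of the types).
#' @return data.frame with one row per cluster: `cluster`, `cell_type`,
#'   `score`, `stage_rank` (NA for unassigned).
#' @export
annotateClusters <- function(de, markers) {
  stopifnot(nrow(markers) > 0)
  absent <- setdiff(markers$gene_id, de$gene_id)
  if (length(absent)) {
    warning(length(absent), " marker gene(s) absent from the DE table: ",
            paste(absent, collapse = ", "))
    markers <- markers[!markers$gene_id %in% absent, , drop = FALSE]
  }
  typeRank <- vapply(split(markers$stage_rank, markers$cell_type), min,
                     numeric(1))
  clusters <- sort(unique(de$cluster))
  rows <- lapply(clusters, function(c) {
    sub <- de[de$cluster == c & de$enriched, , drop = FALSE]
    scores <- vapply(names(typeRank), function(ty) {
      g <- markers$gene_id[markers$cell_type == ty]
      sum(pmax(sub$log2fc[sub$gene_id %in% g], 0))
    }, numeric(1))
    if (!length(scores) || max(scores) == 0) {
      return(data.frame(cluster = c, cell_type = "unassigned", score = 0,
                        stage_rank = NA_real_))
    }
    best <- which(scores == max(scores))
    best <- best[which.min(typeRank[best])]
    data.frame(cluster = c, cell_type = names(typeRank)[best],
               score = unname(max(scores)),
               stage_rank = unname(typeRank[best]))
  })
  do.call(rbind, rows)
}

#' One-sided hypergeometric over-representation test
#'
#' A generic category over-representation test (the statistic behind most
#' gene-ontology enrichment tools): for each category, the upper-tail
#' probability of observing at least `k` category members among the `n`
#' query genes drawn from a universe of `N` genes containing `K` category
#' members, with BH adjustment across categories.
#'
#' @param query character vector of genes, a subset of `universe`.
#' @param categories named list of gene sets.
#' @param universe character vector of all testable genes (non-empty).
#' @return data.frame with columns `term`, `k`, `K`, `n`, `N`, `p`, `p_adj`.
#' @export
hypergeomOverrepresentation <- function(query, categories, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(categories), function(term) {
    cat <- intersect(unique(categories[[term]]), universe)
    K <- length(cat)
    k <- length(intersect(query, cat))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- benjaminiHochberg(out$p)
  out
}
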