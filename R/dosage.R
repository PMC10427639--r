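#' Two-sided Wilcoxon rank-sum (Mann-Whitney) p-value
#'
#' The workhorse test of the dosage analysis. Uses the exact null
#' distribution ([stats::pwilcox()]) when `length(a) + length(b) <= 12`
#' and there are no ties, and the normal approximation with tie and
#' continuity correction otherwise (the same formula as
#' [stats::wilcox.test()]; the two branches agree closely at the
#' boundary). Two identical samples, or an exactly central statistic,
#' give p = 1.
#'
#' @param a,b numeric vectors, each of length >= 1.
#' @return two-sided p-value in \[0, 1\].
#' @examples
#' wilcoxonRankSum(c(1, 2), c(3, 4))  # exact: 1/3
#' @export
wilcoxonRankSum <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  z <- c(a, b)
  if (any(!is.finite(z))) stop("inputs must be finite")
  if (all(z == z[1L])) return(1)
  n1 <- length(a)
  n2 <- length(b)
  r <- rank(z)
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U of sample a
  ties <- anyDuplicated(z) > 0L
  if (!ties && n1 + n2 <= 12L) {
    p <- if (w > n1 * n2 / 2) {
      2 * stats::pwilcox(w - 1, n1, n2, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(w, n1, n2)
    }
    return(min(1, p))
  }
  nt <- table(r)
  tiecorr <- sum(nt^3 - nt) / ((n1 + n2) * (n1 + n2 - 1))
  sigma <- sqrt(n1 * n2 / 12 * (n1 + n2 + 1 - tiecorr))
  if (sigma == 0) return(1)
  d <- w - n1 * n2 / 2
  zstat <- (d - sign(d) * 0.5) / sigma
  min(1, 2 * min(stats::pnorm(zstat), stats::pnorm(zstat, lower.tail = FALSE)))
}

#' Bonferroni adjustment with an explicit family size
#'
#' `p_adj = min(1, m * p)`. The family size `m` is explicit because the
#' dosage analysis corrects each per-cluster test across the family of
#' clusters (or cluster pairs x classes), which the caller knows.
#'
#' @param p numeric vector of p-values.
#' @param m family size, `m >= length(p)`.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) stop("family size m must be >= number of p-values")
  pmin(1, m * p)
}

#' Per-cell RNA content by chromosome class
#'
#' Sums each cell's UMIs over autosomal, X-linked and Y-linked genes (the
#' per-cell "RNA content" of each class). Mitochondrial and unannotated
#' genes are excluded from those three sums and reported separately.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param annotation data.frame with `gene_id` and `class` (see
#'   [geneAnnotation()] / [readGeneAnnotation()]); must cover every gene.
#' @param clusters a [ClusterAssignment-class] covering every cell.
#' @return a `DataFrame` with one row per cell: `barcode`, `cluster`,
#'   `umi_autosome`, `umi_X`, `umi_Y`, `umi_MT`, `umi_unknown`.
#' @export
rnaContentPerCell <- function(sce, annotation, clusters) {
  m <- .counts(sce)
  cls <- annotation$class[match(rownames(m), annotation$gene_id)]
  if (any(is.na(cls))) {
    stop(sum(is.na(cls)), " matrix gene(s) missing from the annotation")
  }
  lab <- clusterLabels(clusters)[colnames(m)]
  sumClass <- function(k) {
    idx <- which(cls == k)
    if (!length(idx)) return(numeric(ncol(m)))
    Matrix::colSums(m[idx, , drop = FALSE])
  }
  S4Vectors::DataFrame(
    barcode = colnames(m),
    cluster = as.integer(as.character(lab)),
    umi_autosome = sumClass("autosome"),
    umi_X = sumClass("X"),
    umi_Y = sumClass("Y"),
    umi_MT = sumClass("MT"),
    umi_unknown = sumClass("UNKNOWN"),
    row.names = colnames(m))
}

#' RNA-content comparisons between consecutive clusters
#'
#' For each adjacent pair of clusters in the developmental order and each
#' chromosome class (autosome, X, Y), a two-sided Wilcoxon rank-sum test
#' on the per-cell class sums, Bonferroni-corrected over the whole family
#' of (pairs x classes) tests. Direction is the sign of the median
#' difference (later minus earlier). A cluster with fewer than 2 cells
#' makes its pair indeterminate (p = NA, with a message).
#'
#' @param content output of [rnaContentPerCell()].
#' @param stage_order integer vector of cluster labels in developmental
#'   order.
#' @return a `DataFrame` with one row per (pair, class): `from`, `to`,
#'   `class`, `p`, `p_adj`, `direction` (-1, 0, 1, or NA).
#' @export
compareContentConsecutive <- function(content, stage_order) {
  classes <- c("autosome", "X", "Y")
  pairs <- cbind(stage_order[-length(stage_order)], stage_order[-1L])
  m <- nrow(pairs) * length(classes)
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- content[content$cluster == pairs[i, 1L], , drop = FALSE]
    b <- content[content$cluster == pairs[i, 2L], , drop = FALSE]
    for (k in classes) {
      va <- a[[paste0("umi_", k)]]
      vb <- b[[paste0("umi_", k)]]
      if (length(va) < 2L || length(vb) < 2L) {
        message("pair ", pairs[i, 1L], "->", pairs[i, 2L],
                " has a cluster with < 2 cells; test indeterminate")
        p <- NA_real_
        dir <- NA_integer_
      } else {
        p <- wilcoxonRankSum(va, vb)
        dir <- sign(stats::median(vb) - stats::median(va))
      }
      rows[[length(rows) + 1L]] <- S4Vectors::DataFrame(
        from = pairs[i, 1L], to = pairs[i, 2L], class = k,
        p = p, direction = dir)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- ifelse(is.na(out$p), NA_real_, bonferroni(out$p, m = m))
  out[, c("from", "to", "class", "p", "p_adj", "direction")]
}

#' Per-gene, per-cluster summed counts with log2(x+1) transform
#'
#' The dosage statistics operate on "log2 counts per gene": each gene's
#' raw counts summed over a cluster's cells, transformed by
#' `log2(counts + 1)`. Genes should first pass
#' [filterGenesClusterExpressed()].
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param clusters a [ClusterAssignment-class] covering every cell.
#' @return a [GeneClusterCounts-class].
#' @export
geneClusterLogCounts <- function(sce, clusters) {
  m <- .counts(sce)
  lab <- clusterLabels(clusters)[colnames(m)]
  raw <- vapply(levels(lab), function(l) {
    cols <- which(lab == l)
    if (!length(cols)) return(numeric(nrow(m)))
    Matrix::rowSums(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  rownames(raw) <- rownames(m)
  methods::new("GeneClusterCounts", raw = raw, log2 = log2(raw + 1))
}

#' X/A (or Y/A) expression-ratio statistics per cluster
#'
#' For every cluster, compares the per-gene `log2(count + 1)` values of
#' the chromosome class of interest against those of the autosomal genes:
#' the ratio is reported on the linear scale as
#' `2^(median_class - median_A)` (so ~1 means dosage-compensated
#' expression and ~0.5 the expression expected from a single X copy
#' without compensation), the p-value comes from the two-sided Wilcoxon
#' rank-sum test on the two gene-level log vectors, and Bonferroni
#' correction is applied across the clusters (one family per class pair).
#' The quotient of the two log medians is available as an alternative
#' ratio scale for sensitivity analysis.
#'
#' @param glc a [GeneClusterCounts-class] (see [geneClusterLogCounts()]).
#' @param annotation data.frame with `gene_id` and `class`.
#' @param classOfInterest `"X"` or `"Y"`.
#' @param dropZero drop genes with zero counts in a cluster from that
#'   cluster's medians (default keeps them at log value 0).
#' @param m Bonferroni family size; defaults to the number of clusters.
#' @param ratioScale `"linear"` (default, `2^(median difference)`) or
#'   `"log-quotient"` (`median_class / median_A` on the log scale).
#' @param alpha,bandNoDc,floorSilenced regime thresholds passed to
#'   [classifyRegime()].
#' @return a [RatioResult-class] with one row per cluster.
#' @export
xaRatioPerCluster <- function(glc, annotation, classOfInterest = c("X", "Y"),
                              dropZero = FALSE, m = NULL,
                              ratioScale = c("linear", "log-quotient"),
                              alpha = 0.05, bandNoDc = c(0.4, 0.65),
                              floorSilenced = 0.4) {
  classOfInterest <- match.arg(classOfInterest)
  ratioScale <- match.arg(ratioScale)
  cls <- annotation$class[match(rownames(glc@raw), annotation$gene_id)]
  iC <- which(cls == classOfInterest)
  iA <- which(cls == "autosome")
  if (length(iC) < 2L || length(iA) < 2L) {
    stop("need >= 2 genes in the class of interest and in the autosomes")
  }
  k <- ncol(glc@raw)
  if (is.null(m)) m <- k
  rows <- lapply(seq_len(k), function(c) {
    vC <- glc@log2[iC, c]
    vA <- glc@log2[iA, c]
    if (dropZero) {
      vC <- vC[glc@raw[iC, c] > 0]
      vA <- vA[glc@raw[iA, c] > 0]
    }
    mC <- stats::median(vC)
    mA <- stats::median(vA)
    ratio <- if (ratioScale == "linear") 2^(mC - mA) else mC / mA
    p <- wilcoxonRankSum(vC, vA)
    S4Vectors::DataFrame(cluster = c, class = classOfInterest,
                         median_class = mC, median_A = mA,
                         ratio = ratio, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni(out$p, m = m)
  out$regime <- classifyRegime(out$ratio, out$p_adj, alpha = alpha,
                               bandNoDc = bandNoDc,
                               floorSilenced = floorSilenced)
  methods::new("RatioResult", out)
}

#' Classify the dosage regime of a cluster
#'
#' A ratio whose deviation from 1 is not significant is called
#' `dosage_compensated`; a significant ratio above 1 is `overexpression`;
#' a significant ratio inside `bandNoDc` (around the ~0.5 expected from a
#' single uncompensated X copy) is `no_compensation`; below
#' `floorSilenced` it is `silenced` (X expression reduced beyond what the
#' loss of compensation alone explains — the MSCI signature); anything
#' else is `indeterminate`. The band edges are explicit because the
#' biological expectations are only approximate ("~1", "~0.5").
#'
#' @param ratio,pAdj numeric vectors (recycled) of linear-scale ratios and
#'   Bonferroni-adjusted p-values.
#' @param alpha significance level (default 0.05).
#' @param bandNoDc interval of ratios called `no_compensation` (default
#'   `c(0.4, 0.65)`).
#' @param floorSilenced ratios strictly below this are `silenced`
#'   (default 0.4).
#' @return character vector of regime calls.
#' @examples
#' classifyRegime(c(1.113, 0.488, 1.0), c(0.002, 1e-71, 1.0))
#' @export
classifyRegime <- function(ratio, pAdj, alpha = 0.05,
                           bandNoDc = c(0.4, 0.65), floorSilenced = 0.4) {
  stopifnot(length(bandNoDc) == 2L, bandNoDc[1] <= bandNoDc[2])
  n <- max(length(ratio), length(pAdj))
  ratio <- rep_len(ratio, n)
  pAdj <- rep_len(pAdj, n)
  out <- rep("indeterminate", n)
  out[pAdj >= alpha] <- "dosage_compensated"
  sig <- pAdj < alpha
  out[sig & ratio > 1] <- "overexpression"
  out[sig & ratio >= bandNoDc[1] & ratio <= bandNoDc[2]] <- "no_compensation"
  out[sig & ratio < floorSilenced] <- "silenced"
  out
}
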