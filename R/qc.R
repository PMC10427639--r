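#' Cell inclusion filter: minimum detected genes
#'
#' Retains exactly the cells detecting at least `minGenes` distinct genes
#' (count >= 1), preserving cell order. The default of 200 is the usual
#' 10x inclusion threshold ("a minimum expression of 200 genes"), read as
#' >= 200 distinct genes with at least one count. Applied before gene
#' filtering; filters are idempotent.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param minGenes non-negative integer threshold (default 200).
#' @return the filtered experiment (possibly with zero cells, with a message).
#' @export
filterCellsMinGenes <- function(sce, minGenes = 200L) {
  stopifnot(minGenes >= 0)
  detected <- Matrix::colSums(.counts(sce) > 0)
  keep <- detected >= minGenes
  if (!any(keep)) message("no cells pass the min-genes filter")
  sce[, keep]
}

#' Gene inclusion filter: expressed in at least one cell
#'
#' Retains genes with at least one UMI across the (already cell-filtered)
#' matrix.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @return the filtered experiment.
#' @export
filterGenesExpressed <- function(sce) {
  sce[Matrix::rowSums(.counts(sce)) >= 1, ]
}

#' Gene inclusion filter: expressed in at least one cell cluster
#'
#' Retains genes whose summed count within at least one cluster is >= 1.
#' When the clusters partition all cells this coincides with
#' [filterGenesExpressed()]; it is kept as a distinct operation because the
#' chromosome-dosage analysis states its threshold per cluster, and cluster
#' assignments that cover only a subset of cells make the two differ.
#'
#' @param sce a `SingleCellExperiment`.
#' @param clusters a [ClusterAssignment-class] covering every cell of `sce`.
#' @return the filtered experiment.
#' @export
filterGenesClusterExpressed <- function(sce, clusters) {
  lab <- clusterLabels(clusters)
  missing <- setdiff(colnames(sce), names(lab))
  if (length(missing)) {
    stop(length(missing), " cell(s) have no cluster label")
  }
  m <- .counts(sce)
  grp <- lab[colnames(sce)]
  perCluster <- vapply(levels(grp), function(l) {
    cols <- which(grp == l)
    if (!length(cols)) return(numeric(nrow(m)))
    Matrix::rowSums(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  sce[apply(perCluster >= 1, 1L, any), ]
}

#' QC summary statistics
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @return a [QcSummary-class]: dimensions, median genes detected per cell,
#'   total UMI, and the per-cell detected-gene vector. An empty matrix
#'   yields zeros with a warning.
#' @export
qcSummary <- function(sce) {
  m <- .counts(sce)
  if (ncol(m) == 0L || nrow(m) == 0L) {
    warning("empty count matrix; QC summary is all zeros")
    return(methods::new("QcSummary", nCells = ncol(m), nGenes = nrow(m),
                        medianGenesPerCell = 0, totalUmi = 0,
                        genesPerCell = stats::setNames(numeric(0), character(0))))
  }
  gpc <- Matrix::colSums(m > 0)
  methods::new("QcSummary", nCells = ncol(m), nGenes = nrow(m),
               medianGenesPerCell = stats::median(gpc),
               totalUmi = sum(m), genesPerCell = gpc)
}
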