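#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

setOldClass("data.frame")

#' Simulation configuration for the germline UMI-count generator
#'
#' Describes a synthetic testis dataset: ordered cell clusters of given
#' sizes, genes per chromosome arm, a log-normal per-gene baseline mean, a
#' shared negative-binomial dispersion, per-cell log-normal library-size
#' spread, a cluster-by-chromosome-class matrix of multiplicative expression
#' factors (the injected X/A, Y/A and MT regimes), and a marker-gene
#' specification (gene, cluster, fold) spiked multiplicatively on top.
#'
#' @slot seed integer; drives all randomness in [simulateGermline()].
#' @slot clusterSizes named integer vector of cells per cluster, in stage
#'   order position 1..K (labels are the names).
#' @slot genesPerClass named integer vector of gene counts per arm
#'   (2R, 2L, 3R, 3L, X, Y, MT); zero entries allowed.
#' @slot baseMeanLogMu,baseMeanLogSigma meanlog/sdlog of the log-normal
#'   baseline per-gene mean expression (UMI per cell at library factor 1).
#' @slot yBaselineShrink positive factor by which Y-gene baseline means are
#'   divided (Y contigs are weakly expressed throughout spermatogenesis).
#' @slot nbDispersion positive NB size parameter, shared across genes.
#' @slot libsizeLogSigma sdlog of the per-cell library factor (meanlog is
#'   set so the factor has expectation 1).
#' @slot classFactor K x 4 matrix of positive factors, columns
#'   `c("autosome","X","Y","MT")`, rows = clusters.
#' @slot markerSpec data.frame with columns `gene` (column index into the
#'   simulated matrix), `cluster` (integer), `fold` (>= 1).
#' @slot stageOrder integer permutation of `1:K` giving the true
#'   developmental order of the clusters.
#'
#' @seealso [SimulationConfig()], [defaultGermlineConfig()],
#'   [simulateGermline()]
#' @export
setClass("SimulationConfig", representation(
  seed = "integer",
  clusterSizes = "integer",
  genesPerClass = "integer",
  baseMeanLogMu = "numeric",
  baseMeanLogSigma = "numeric",
  yBaselineShrink = "numeric",
  nbDispersion = "numeric",
  libsizeLogSigma = "numeric",
  classFactor = "matrix",
  markerSpec = "data.frame",
  stageOrder = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  k <- length(object@clusterSizes)
  if (k < 1L || any(object@clusterSizes < 1L)) {
    msg <- c(msg, "all cluster sizes must be >= 1")
  }
  if (!identical(sort(names(object@genesPerClass)), sort(.chromArms))) {
    msg <- c(msg, "genesPerClass must be named by the seven arms 2R,2L,3R,3L,X,Y,MT")
  }
  if (any(object@genesPerClass < 0L)) msg <- c(msg, "gene counts must be >= 0")
  if (object@nbDispersion <= 0) msg <- c(msg, "nbDispersion must be > 0")
  if (object@yBaselineShrink <= 0) msg <- c(msg, "yBaselineShrink must be > 0")
  if (object@libsizeLogSigma < 0) msg <- c(msg, "libsizeLogSigma must be >= 0")
  cf <- object@classFactor
  if (!identical(dim(cf), c(k, 4L)) ||
      !identical(colnames(cf), .chromClasses)) {
    msg <- c(msg, "classFactor must be K x 4 with columns autosome,X,Y,MT")
  } else if (any(cf <= 0)) {
    msg <- c(msg, "all class factors must be > 0")
  }
  ms <- object@markerSpec
  if (nrow(ms)) {
    if (!all(c("gene", "cluster", "fold") %in% names(ms))) {
      msg <- c(msg, "markerSpec needs columns gene, cluster, fold")
    } else {
      if (any(ms$fold < 1)) msg <- c(msg, "marker folds must be >= 1")
      if (any(ms$cluster < 1 | ms$cluster > k)) {
        msg <- c(msg, "markerSpec cluster out of range")
      }
      if (any(ms$gene < 1 | ms$gene > sum(object@genesPerClass))) {
        msg <- c(msg, "markerSpec gene index out of range")
      }
    }
  }
  if (!identical(sort(object@stageOrder), seq_len(k))) {
    msg <- c(msg, "stageOrder must be a permutation of 1:K")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", length(object@clusterSizes), "clusters,",
      sum(object@clusterSizes), "cells,",
      sum(object@genesPerClass), "genes\n")
  cat("  cluster sizes:", paste(object@clusterSizes, collapse = ", "), "\n")
  cat("  X factors:   ",
      paste(format(object@classFactor[, "X"]), collapse = ", "), "\n")
  cat("  markers:", nrow(object@markerSpec), "spiked (gene, cluster) pairs;",
      "seed", object@seed, "\n")
})

#' Cluster assignment of cells, with optional stage order
#'
#' A partition of cell barcodes into `1:k` cluster labels. `stageOrder`,
#' when set, is the developmental order of the labels used by the
#' "consecutive cluster" comparisons; it comes from trajectory/marker
#' annotation, not from clustering itself.
#'
#' @slot labels factor of cluster labels, named by cell barcode.
#' @slot k integer number of clusters.
#' @slot stageOrder integer vector: a permutation of `1:k`, or length 0 if
#'   no order has been assigned yet.
#' @export
setClass("ClusterAssignment", representation(
  labels = "factor",
  k = "integer",
  stageOrder = "integer"
))

setValidity("ClusterAssignment", function(object) {
  msg <- character()
  if (is.null(names(object@labels)) || anyDuplicated(names(object@labels))) {
    msg <- c(msg, "labels must be uniquely named by cell barcode")
  }
  if (!identical(levels(object@labels), as.character(seq_len(object@k)))) {
    msg <- c(msg, "label levels must be 1..k")
  }
  so <- object@stageOrder
  if (length(so) && !identical(sort(so), seq_len(object@k))) {
    msg <- c(msg, "stageOrder must be a permutation of 1:k")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ClusterAssignment
#'
#' @param labels vector coercible to integer cluster labels in `1:k`,
#'   named by cell barcode.
#' @param k number of clusters; defaults to `max(labels)`.
#' @param stageOrder optional permutation of `1:k` (developmental order).
#' @return a [ClusterAssignment-class] object.
#' @export
ClusterAssignment <- function(labels, k = max(as.integer(labels)),
                              stageOrder = integer()) {
  lab <- as.integer(labels)
  f <- factor(lab, levels = seq_len(k))
  names(f) <- names(labels)
  methods::new("ClusterAssignment", labels = f, k = as.integer(k),
               stageOrder = as.integer(stageOrder))
}

#' @describeIn ClusterAssignment cluster labels as a named factor.
#' @param x a `ClusterAssignment`.
#' @export
clusterLabels <- function(x) x@labels

#' @describeIn ClusterAssignment developmental order of the labels
#'   (may be length 0).
#' @export
stageOrder <- function(x) x@stageOrder

#' @describeIn ClusterAssignment set the developmental order.
#' @param value integer permutation of `1:k`.
#' @export
`stageOrder<-` <- function(x, value) {
  x@stageOrder <- as.integer(value)
  methods::validObject(x)
  x
}

setMethod("show", "ClusterAssignment", function(object) {
  sz <- table(object@labels)
  cat("ClusterAssignment: ", length(object@labels), " cells in ",
      object@k, " clusters\n", sep = "")
  cat("  sizes:", paste(as.integer(sz), collapse = ", "), "\n")
  if (length(object@stageOrder)) {
    cat("  stage order:", paste(object@stageOrder, collapse = " -> "), "\n")
  }
})

#' Low-dimensional embedding of cells
#'
#' Principal-component scores of the cells (rows) with the variance
#' explained by each component.
#'
#' @slot coords numeric matrix, cells x components, rownames = barcodes.
#' @slot explainedVariance numeric vector, one entry per component.
#' @slot genes character vector of the genes the embedding was fit on.
#' @export
setClass("Embedding", representation(
  coords = "matrix",
  explainedVariance = "numeric",
  genes = "character"
))

setValidity("Embedding", function(object) {
  msg <- character()
  if (!all(is.finite(object@coords))) msg <- c(msg, "coords must be finite")
  if (length(object@explainedVariance) != ncol(object@coords)) {
    msg <- c(msg, "one explainedVariance entry per component")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "Embedding", function(object) {
  cat("Embedding: ", nrow(object@coords), " cells x ", ncol(object@coords),
      " components (", length(object@genes), " genes)\n", sep = "")
  pv <- object@explainedVariance / sum(object@explainedVariance)
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * pv[seq_len(min(5, length(pv)))]),
            collapse = ", "),
      if (length(pv) > 5) "...\n" else "\n")
})

#' @describeIn Embedding the cells x components score matrix.
#' @param x an `Embedding`.
#' @export
embeddingCoords <- function(x) x@coords

#' QC summary of a UMI count matrix
#'
#' @slot nCells,nGenes matrix dimensions after whatever filtering produced it.
#' @slot medianGenesPerCell median number of genes detected (count >= 1) per cell.
#' @slot totalUmi total UMI count.
#' @slot genesPerCell per-cell detected-gene counts, named by barcode.
#' @export
setClass("QcSummary", representation(
  nCells = "integer",
  nGenes = "integer",
  medianGenesPerCell = "numeric",
  totalUmi = "numeric",
  genesPerCell = "numeric"
))

setMethod("show", "QcSummary", function(object) {
  cat("QcSummary: ", object@nCells, " cells x ", object@nGenes, " genes; ",
      "median ", object@medianGenesPerCell, " genes/cell; ",
      format(object@totalUmi, big.mark = ","), " UMIs\n", sep = "")
})

#' Per-gene, per-cluster summed counts and their log2(x+1) transform
#'
#' @slot raw genes x clusters matrix of summed UMI counts.
#' @slot log2 genes x clusters matrix, exactly `log2(raw + 1)`.
#' @export
setClass("GeneClusterCounts", representation(
  raw = "matrix",
  log2 = "matrix"
))

setValidity("GeneClusterCounts", function(object) {
  msg <- character()
  if (any(object@raw < 0)) msg <- c(msg, "raw counts must be >= 0")
  if (!isTRUE(all.equal(object@log2, log2(object@raw + 1)))) {
    msg <- c(msg, "log2 slot must equal log2(raw + 1)")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneClusterCounts", function(object) {
  cat("GeneClusterCounts: ", nrow(object@raw), " genes x ",
      ncol(object@raw), " clusters\n", sep = "")
})

#' Pseudotime trajectory over cluster centroids
#'
#' @slot rootCluster integer label of the root cluster.
#' @slot clusterOrder integer labels ordered by tree distance from the root.
#' @slot pseudotime numeric, named by barcode; min over root-cluster cells is 0.
#' @slot treeEdges two-column matrix of cluster labels: the MST edges.
#' @export
setClass("TrajectoryResult", representation(
  rootCluster = "integer",
  clusterOrder = "integer",
  pseudotime = "numeric",
  treeEdges = "matrix"
))

setValidity("TrajectoryResult", function(object) {
  msg <- character()
  if (any(!is.finite(object@pseudotime))) msg <- c(msg, "pseudotime must be finite")
  if (any(object@pseudotime < -1e-9)) msg <- c(msg, "pseudotime must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TrajectoryResult", function(object) {
  cat("TrajectoryResult: root cluster ", object@rootCluster,
      "; order ", paste(object@clusterOrder, collapse = " -> "), "\n",
      sep = "")
  cat("  pseudotime range [", format(min(object@pseudotime), digits = 4),
      ", ", format(max(object@pseudotime), digits = 4), "] over ",
      length(object@pseudotime), " cells\n", sep = "")
})

#' @describeIn TrajectoryResult pseudotime values named by barcode.
#' @param x a `TrajectoryResult`.
#' @export
pseudotime <- function(x) x@pseudotime

#' Cluster-versus-rest differential expression result
#'
#' A `DataFrame` with one row per (cluster, gene): `cluster`, `gene_id`,
#' `log2fc`, `p`, `p_adj` (Benjamini-Hochberg within cluster) and the
#' `enriched` flag, true iff `log2fc > 1` and `p_adj < 0.05`.
#'
#' @export
setClass("DEResult", contains = "DFrame")

setValidity("DEResult", function(object) {
  need <- c("cluster", "gene_id", "log2fc", "p", "p_adj", "enriched")
  if (!all(need %in% colnames(object))) {
    return(paste("missing columns:",
                 paste(setdiff(need, colnames(object)), collapse = ", ")))
  }
  msg <- character()
  if (any(object$p_adj < object$p - 1e-12)) {
    msg <- c(msg, "p_adj must be >= p")
  }
  rule <- object$log2fc > metadata(object)$log2fc_cutoff &
    object$p_adj < metadata(object)$alpha
  if (!identical(as.logical(object$enriched), as.logical(rule))) {
    msg <- c(msg, "enriched flag inconsistent with the enrichment rule")
  }
  if (length(msg)) msg else TRUE
})

#' Chromosome-class expression-ratio result
#'
#' A `DataFrame` with one row per (cluster, class pair): median log2(count+1)
#' of the class of interest and of the autosomes, the linear-scale ratio
#' `2^(median_class - median_A)`, Wilcoxon p, Bonferroni-adjusted p, and the
#' dosage regime call.
#'
#' @export
setClass("RatioResult", contains = "DFrame")

setValidity("RatioResult", function(object) {
  need <- c("cluster", "class", "median_class", "median_A", "ratio",
            "p", "p_adj", "regime")
  if (!all(need %in% colnames(object))) {
    return(paste("missing columns:",
                 paste(setdiff(need, colnames(object)), collapse = ", ")))
  }
  if (any(object$ratio <= 0)) return("ratio must be > 0")
  TRUE
})
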