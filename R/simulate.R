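#' Construct a simulation configuration
#'
#' Builds a validated [SimulationConfig-class]. The generative model is:
#' for gene g (chromosome class K) in a cell of cluster c with library
#' factor L, counts are negative binomial with mean
#' `L * mu_g * fold_{g,c} * classFactor[c, K]` and shared dispersion
#' (`size`) `nbDispersion`. Baseline means `mu_g` are log-normal; Y-contig
#' baselines are divided by `yBaselineShrink` to reflect their weak
#' expression throughout spermatogenesis. Library factors are log-normal
#' with expectation 1. Marker folds (>= 1) are multiplicative spikes on top
#' of the chromosome-class regime, so marker programs and dosage regimes
#' stay orthogonal and separately recoverable.
#'
#' @param seed integer seed driving all randomness of the simulation.
#' @param clusterSizes positive integers, cells per cluster (stage-ordered
#'   position is given by `stageOrder`).
#' @param genesPerClass named non-negative integers for arms
#'   2R, 2L, 3R, 3L, X, Y, MT.
#' @param baseMeanLogMu,baseMeanLogSigma meanlog/sdlog of the per-gene
#'   baseline mean.
#' @param yBaselineShrink divide Y baselines by this (default 10).
#' @param nbDispersion NB size parameter (default 2).
#' @param libsizeLogSigma per-cell library-factor sdlog (default 0.35).
#' @param classFactor K x 4 matrix (columns autosome, X, Y, MT) of positive
#'   factors; defaults to all 1.
#' @param markerSpec data.frame(gene, cluster, fold >= 1); default empty.
#' @param stageOrder permutation of `1:K`: true developmental order.
#' @return a `SimulationConfig`.
#' @export
SimulationConfig <- function(seed = 1L,
                             clusterSizes = c(100L, 100L),
                             genesPerClass = c(`2R` = 250L, `2L` = 250L,
                                               `3R` = 250L, `3L` = 250L,
                                               X = 100L, Y = 10L, MT = 5L),
                             baseMeanLogMu = -1.15,
                             baseMeanLogSigma = 0.8,
                             yBaselineShrink = 10,
                             nbDispersion = 2,
                             libsizeLogSigma = 0.35,
                             classFactor = NULL,
                             markerSpec = data.frame(gene = integer(),
                                                     cluster = integer(),
                                                     fold = numeric()),
                             stageOrder = seq_along(clusterSizes)) {
  .checkWholeNumber(clusterSizes, "cluster sizes")
  .checkWholeNumber(genesPerClass, "gene counts")
  k <- length(clusterSizes)
  if (is.null(classFactor)) {
    classFactor <- matrix(1, nrow = k, ncol = 4,
                          dimnames = list(NULL, .chromClasses))
  }
  cs <- as.integer(clusterSizes)
  names(cs) <- if (is.null(names(clusterSizes))) {
    paste0("cluster", seq_len(k))
  } else names(clusterSizes)
  gp <- as.integer(genesPerClass)
  names(gp) <- names(genesPerClass)
  methods::new("SimulationConfig",
               seed = as.integer(seed), clusterSizes = cs,
               genesPerClass = gp[.chromArms],
               baseMeanLogMu = baseMeanLogMu,
               baseMeanLogSigma = baseMeanLogSigma,
               yBaselineShrink = yBaselineShrink,
               nbDispersion = nbDispersion,
               libsizeLogSigma = libsizeLogSigma,
               classFactor = classFactor,
               markerSpec = markerSpec,
               stageOrder = as.integer(stageOrder))
}

#' Default testis-scale configuration
#'
#' A configuration shaped like the mosquito testis germline dataset the
#' pipeline targets: 4443 cells in 8 stage-ordered clusters of very unequal
#' size (11 to 1338 cells: hub cells, germline stem cells, primary
#' spermatogonia, late spermatogonia/primary spermatocytes, spermatocytes,
#' late spermatocytes/early spermatids, late spermatids, mature
#' spermatozoa), roughly 2500 genes per autosomal arm, 1000 X genes, 50
#' Y-contig genes and 15 mitochondrial genes. The baseline-mean constants
#' are calibrated so the simulated median genes-detected per cell lands
#' near the real dataset's (~2850 of ~11.5k genes).
#'
#' Injected chromosome regimes (X column of `classFactor`): hub cells 1
#' (dosage compensated), GSCs 1.11 (X overexpression), primary
#' spermatogonia 0.5 (no compensation), then 0.3, 0.2, 0.15, 0.1, 0.1
#' (progressive X silencing — MSCI). Mitochondrial factor rises to 5 in
#' mature spermatozoa. Marker programs: 30 unique markers per cluster at
#' fold 16 (hub 32), the GSC program placed on the X (emulating the X-bias
#' of GSC-enriched genes), plus a 100-gene autosomal ramp whose fold grows
#' with stage rank so consecutive stages are transcriptionally adjacent —
#' this is what a trajectory method can recover. The first GSC marker plays
#' the role of the premeiotic root marker (a *vasa*-like gene peaking in
#' GSCs); its gene id is stored in the returned object's metadata by
#' [simulateGermline()].
#'
#' @param seed integer seed.
#' @return a `SimulationConfig` whose cluster sizes sum to 4443.
#' @export
defaultGermlineConfig <- function(seed = 1L) {
  sizes <- c(HC = 11L, GSC = 50L, `P-Spg` = 200L, `L-Spg/P-Spc` = 600L,
             Spc = 900L, `L-Spc/E-Spt` = 1338L, `L-Spt` = 800L, Spz = 544L)
  gp <- c(`2R` = 2500L, `2L` = 2500L, `3R` = 2500L, `3L` = 2500L,
          X = 1000L, Y = 50L, MT = 15L)
  cf <- matrix(1, nrow = 8, ncol = 4, dimnames = list(names(sizes), .chromClasses))
  cf[, "X"] <- c(1, 1.11, 0.5, 0.3, 0.2, 0.15, 0.1, 0.1)
  cf[, "MT"] <- c(1, 1, 1, 1, 1, 1, 2, 5)
  # stage ramp: 100 autosomal genes whose fold doubles every 2.5 stages
  ramp <- do.call(rbind, lapply(1:8, function(r) {
    data.frame(gene = 1:100, cluster = r, fold = 2^(0.4 * (r - 1)))
  }))
  markerBlock <- function(genes, cluster, fold) {
    data.frame(gene = genes, cluster = cluster, fold = fold)
  }
  # Germline programs persist into the following stage at half strength,
  # as the real markers do (e.g. geminin/squid enriched in GSCs and still
  # in primary spermatogonia); the somatic hub program does not persist.
  germProgram <- function(genes, stage) {
    out <- markerBlock(genes, stage, 16)
    if (stage < 8L) out <- rbind(out, markerBlock(genes, stage + 1L, 8))
    out
  }
  markers <- rbind(
    markerBlock(201:230, 1L, 32),      # hub program (somatic, very distinct)
    germProgram(10001:10030, 2L),      # GSC program on the X; 10001 = root marker
    germProgram(301:330, 3L),
    germProgram(401:430, 4L),
    germProgram(501:530, 5L),
    germProgram(601:630, 6L),
    germProgram(701:730, 7L),
    markerBlock(801:830, 8L, 16)
  )
  SimulationConfig(seed = seed, clusterSizes = sizes, genesPerClass = gp,
                   baseMeanLogMu = -1.15, baseMeanLogSigma = 0.8,
                   classFactor = cf, markerSpec = rbind(ramp, markers),
                   stageOrder = 1:8)
}

#' Simulate a germline UMI count matrix with ground truth
#'
#' Draws a sparse genes x cells UMI count matrix from the negative-binomial
#' model described in [SimulationConfig()]. Deterministic given
#' `config@seed` (the caller's RNG state is untouched).
#'
#' @param config a validated [SimulationConfig-class].
#' @return a [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment]
#'   with assay `counts` (sparse, genes x cells), `rowData` columns
#'   `gene_id`, `arm`, `class`, `base_mean` (the drawn baseline mean), and
#'   ground truth in `colData` (`true_cluster`, `true_rank` — the
#'   cluster's position in the developmental order — and `lib_factor`)
#'   and in `metadata()` (`class_factor`, `marker_spec`, `stage_order`,
#'   `root_marker`, `config`).
#' @examples
#' sce <- simulateGermline(SimulationConfig(seed = 7,
#'   clusterSizes = c(20, 20)))
#' dim(sce)
#' @export
simulateGermline <- function(config) {
  methods::validObject(config)
  k <- length(config@clusterSizes)
  gp <- config@genesPerClass
  nGenes <- sum(gp)
  nCells <- sum(config@clusterSizes)
  arms <- rep(names(gp), times = gp)
  cls <- armToClass(arms)
  geneIds <- sprintf("G%05d", seq_len(nGenes))
  barcodes <- sprintf("cell-%05d", seq_len(nCells))
  clusterOf <- rep(seq_len(k), times = config@clusterSizes)

  .withSeed(config@seed, {
    mu <- stats::rlnorm(nGenes, config@baseMeanLogMu, config@baseMeanLogSigma)
    mu[cls == "Y"] <- mu[cls == "Y"] / config@yBaselineShrink
    s <- config@libsizeLogSigma
    lib <- stats::rlnorm(nCells, -s^2 / 2, s)

    ms <- config@markerSpec
    blocks <- vector("list", k)
    for (c in seq_len(k)) {
      foldVec <- rep(1, nGenes)
      if (nrow(ms)) {
        rows <- ms$cluster == c
        if (any(rows)) {
          idx <- ms$gene[rows]
          foldVec[idx] <- foldVec[idx] * ms$fold[rows]
        }
      }
      muC <- mu * foldVec * config@classFactor[c, ][match(cls, .chromClasses)]
      cells <- which(clusterOf == c)
      mean <- outer(muC, lib[cells])
      cnt <- stats::rnbinom(length(mean), size = config@nbDispersion, mu = mean)
      blocks[[c]] <- Matrix::Matrix(
        matrix(as.double(cnt), nrow = nGenes), sparse = TRUE)
    }
    counts <- do.call(cbind, blocks)
    dimnames(counts) <- list(geneIds, barcodes)

    rootMarker <- NA_character_
    if (nrow(ms)) {
      # the strongest single (gene, cluster) spike in the earliest germline
      # cluster that has markers doubles as the premeiotic root marker
      mk <- ms[ms$fold > 1, , drop = FALSE]
      if (nrow(mk)) {
        rk <- match(mk$cluster, config@stageOrder)
        mk <- mk[order(rk, -mk$fold, mk$gene), , drop = FALSE]
        germ <- mk[mk$cluster != config@stageOrder[1L] | k == 1L, , drop = FALSE]
        pick <- if (nrow(germ)) germ else mk
        rootMarker <- geneIds[pick$gene[1L]]
      }
    }

    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = counts),
      rowData = S4Vectors::DataFrame(gene_id = geneIds, arm = arms,
                                     class = cls, base_mean = mu,
                                     row.names = geneIds),
      colData = S4Vectors::DataFrame(
        barcode = barcodes,
        true_cluster = clusterOf,
        true_rank = match(clusterOf, config@stageOrder),
        lib_factor = lib,
        row.names = barcodes)
    )
    S4Vectors::metadata(sce) <- list(
      class_factor = config@classFactor,
      marker_spec = config@markerSpec,
      stage_order = config@stageOrder,
      root_marker = rootMarker,
      config = config
    )
    sce
  })
}

#' Gene annotation table of a simulated or loaded experiment
#'
#' @param sce a `SingleCellExperiment` with `arm` in its rowData.
#' @return data.frame with columns `gene_id`, `arm`, `class`.
#' @export
geneAnnotation <- function(sce) {
  rd <- SummarizedExperiment::rowData(sce)
  if (!"arm" %in% colnames(rd)) stop("rowData has no 'arm' column")
  data.frame(gene_id = rownames(sce), arm = rd$arm,
             class = armToClass(rd$arm), row.names = NULL)
}

#' True cluster assignment of a simulated experiment
#'
#' @param sce output of [simulateGermline()].
#' @return a [ClusterAssignment-class] built from the ground truth, with
#'   `stageOrder` set to the injected developmental order.
#' @export
trueClusters <- function(sce) {
  cd <- SummarizedExperiment::colData(sce)
  if (!"true_cluster" %in% colnames(cd)) stop("no ground-truth clusters")
  lab <- cd$true_cluster
  names(lab) <- rownames(cd)
  ClusterAssignment(lab, k = max(lab),
                    stageOrder = S4Vectors::metadata(sce)$stage_order)
}
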