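#' Run the full pipeline: simulate/load -> QC -> cluster -> DE -> trajectory -> dosage
#'
#' Orchestrates every stage into one reproducible run. Each stage is
#' wrapped so that a failure aborts with the stage's name. The report is
#' fully determined by the configuration (which embeds all seeds).
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{simulation}{a [SimulationConfig-class], or `NULL` to read
#'       from `input_dir` (a 10x triplet; annotation from the features
#'       file or `annotation_path`).}
#'     \item{input_dir, annotation_path}{inputs when not simulating.}
#'     \item{min_genes}{cell filter threshold (default 200).}
#'     \item{k}{cluster count for the main analysis (default 8).}
#'     \item{k_range}{k sweep reported alongside (default `2:10`).}
#'     \item{n_components, n_top_genes}{PCA settings (defaults 10, 1000).}
#'     \item{seed}{clustering seed (default 1).}
#'     \item{root_marker}{gene id of the premeiotic root marker; defaults
#'       to the simulation's designated root marker.}
#'     \item{marker_table}{optional data.frame(gene_id, cell_type,
#'       stage_rank) for cluster annotation.}
#'     \item{log2fc_cutoff, alpha}{enrichment rule (defaults 1, 0.05).}
#'     \item{run_de}{set `FALSE` to skip the (slow) DE stage.}
#'   }
#' @return a list of stage outputs plus `report`, a plain list mirroring
#'   the result tables (QC summary, per-k cluster sizes, enriched-gene
#'   counts per cluster and chromosome, consecutive-content tests, the
#'   X/A and Y/A ratio/regime table, the pseudotime cluster order), with
#'   the seeds and configuration embedded.
#' @export
runFull <- function(config) {
  cfg <- utils::modifyList(list(
    simulation = NULL, input_dir = NULL, annotation_path = NULL,
    min_genes = 200L, k = 8L, k_range = 2:10, n_components = 10L,
    n_top_genes = 1000L, seed = 1L, root_marker = NULL,
    marker_table = NULL, log2fc_cutoff = 1, alpha = 0.05, run_de = TRUE
  ), config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  sce <- stage("input", {
    if (!is.null(cfg$simulation)) {
      simulateGermline(cfg$simulation)
    } else if (!is.null(cfg$input_dir)) {
      read10x(cfg$input_dir)
    } else {
      stop("config needs either 'simulation' or 'input_dir'")
    }
  })
  annotation <- stage("annotation", {
    if (!is.null(cfg$annotation_path)) {
      readGeneAnnotation(cfg$annotation_path)
    } else if ("arm" %in% colnames(SummarizedExperiment::rowData(sce))) {
      geneAnnotation(sce)
    } else {
      stop("no gene annotation: supply 'annotation_path' or a features ",
           "file with a chromosome column (required by the dosage stage)")
    }
  })
  if (is.null(cfg$root_marker)) {
    cfg$root_marker <- S4Vectors::metadata(sce)$root_marker
  }

  filtered <- stage("qc", {
    out <- filterCellsMinGenes(sce, cfg$min_genes)
    filterGenesExpressed(out)
  })
  qc <- stage("qc", qcSummary(filtered))

  normalized <- stage("normalize", normalizeLog(filtered))
  embedding <- stage("pca", pcaEmbed(normalized, cfg$n_components,
                                     cfg$n_top_genes))
  clusters <- stage("cluster", kmeansCluster(embedding, cfg$k,
                                             seed = cfg$seed))
  sweep <- stage("cluster", sweepK(embedding, cfg$k_range, seed = cfg$seed))

  de <- NULL
  partition <- NULL
  byChrom <- NULL
  annotated <- NULL
  if (isTRUE(cfg$run_de)) {
    de <- stage("diffexpr", globallyDistinguishingDE(
      normalized, clusters, log2fcCutoff = cfg$log2fc_cutoff,
      alpha = cfg$alpha))
    partition <- stage("diffexpr", enrichmentPartition(de))
    byChrom <- stage("diffexpr", enrichmentByChromosome(de, annotation))
    if (!is.null(cfg$marker_table)) {
      annotated <- stage("diffexpr", annotateClusters(de, cfg$marker_table))
    }
  }

  trajectory <- stage("trajectory", {
    if (is.null(cfg$root_marker) || is.na(cfg$root_marker)) {
      stop("no root marker available")
    }
    root <- selectRoot(normalized, clusters, cfg$root_marker)
    pseudotimeMST(embedding, clusters, root)
  })
  stageOrder(clusters) <- trajectory@clusterOrder

  dosage <- stage("dosage", {
    clusterExpr <- filterGenesClusterExpressed(filtered, clusters)
    glc <- geneClusterLogCounts(clusterExpr, clusters)
    content <- rnaContentPerCell(clusterExpr, annotation, clusters)
    list(
      ratio_X = xaRatioPerCluster(glc, annotation, "X"),
      ratio_Y = xaRatioPerCluster(glc, annotation, "Y"),
      content = content,
      content_tests = compareContentConsecutive(content,
                                                stageOrder(clusters))
    )
  })

  report <- list(
    seed = cfg$seed,
    n_cells = qc@nCells,
    n_genes = qc@nGenes,
    median_genes_per_cell = qc@medianGenesPerCell,
    total_umi = qc@totalUmi,
    cluster_sizes = as.integer(table(clusterLabels(clusters))),
    sweep_sizes = lapply(sweep, function(a) {
      as.integer(table(clusterLabels(a)))
    }),
    pseudotime_order = trajectory@clusterOrder,
    root_cluster = trajectory@rootCluster,
    enriched_per_cluster = if (!is.null(de)) {
      as.integer(table(factor(de$cluster[de$enriched],
                              levels = seq_len(cfg$k))))
    },
    enrichment_partition = if (!is.null(partition)) {
      as.list(stats::setNames(as.integer(partition), names(partition)))
    },
    enrichment_by_chromosome = if (!is.null(byChrom)) {
      as.data.frame.matrix(unclass(byChrom))
    },
    cluster_annotation = annotated,
    ratio_table = rbind(as.data.frame(dosage$ratio_X),
                        as.data.frame(dosage$ratio_Y)),
    content_tests = as.data.frame(dosage$content_tests),
    config = cfg[c("min_genes", "k", "n_components", "n_top_genes",
                   "seed", "root_marker", "log2fc_cutoff", "alpha")]
  )

  list(sce = sce, filtered = filtered, normalized = normalized,
       embedding = embedding, clusters = clusters, de = de,
       trajectory = trajectory, dosage = dosage, annotation = annotation,
       report = report)
}

#' Write a run's report bundle to disk
#'
#' Emits `report.json` plus CSVs of the main result tables (ratio/regime
#' table, consecutive-content tests, per-cell content, clusters,
#' pseudotime) so every stage artifact is independently inspectable.
#'
#' @param run output of [runFull()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeReport <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(run$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  utils::write.csv(run$report$ratio_table,
                   file.path(dir, "ratio_results.csv"), row.names = FALSE)
  utils::write.csv(run$report$content_tests,
                   file.path(dir, "content_tests.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(run$dosage$content),
                   file.path(dir, "content_per_cell.csv"), row.names = FALSE)
  lab <- clusterLabels(run$clusters)
  utils::write.csv(data.frame(barcode = names(lab),
                              cluster = as.integer(as.character(lab))),
                   file.path(dir, "clusters.csv"), row.names = FALSE)
  pt <- pseudotime(run$trajectory)
  utils::write.csv(data.frame(barcode = names(pt), pseudotime = pt),
                   file.path(dir, "pseudotime.csv"), row.names = FALSE)
  if (!is.null(run$de)) {
    utils::write.csv(as.data.frame(run$de), file.path(dir, "de.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
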