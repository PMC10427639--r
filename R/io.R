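#' Read a 10x-style MatrixMarket triplet directory
#'
#' Expects `matrix.mtx`, `features.tsv` and `barcodes.tsv` (optionally
#' gzipped, `*.gz`). The on-disk 10x convention stores genes as rows and
#' cells as columns; orientation is inferred by matching the declared
#' dimensions against the features/barcodes line counts, so transposed
#' matrices load correctly too. Values must be non-negative integers and
#' barcodes unique.
#'
#' @param dir path to the triplet directory.
#' @return a `SingleCellExperiment` (genes x cells) with a `counts` assay;
#'   `rowData` carries `gene_id`, `gene_name` and, when the features file
#'   has a third column, `arm`/`class`; if a `truth.tsv` is present its
#'   cluster and rank columns are attached to `colData`.
#' @export
read10x <- function(dir) {
  mtx <- .findFile(dir, "matrix.mtx")
  feat <- .findFile(dir, "features.tsv")
  bc <- .findFile(dir, "barcodes.tsv")
  m <- Matrix::readMM(.open(mtx))
  features <- utils::read.table(.open(feat), sep = "\t", header = FALSE,
                                colClasses = "character", quote = "")
  barcodes <- utils::read.table(.open(bc), sep = "\t", header = FALSE,
                                colClasses = "character", quote = "")[[1]]
  nG <- nrow(features)
  nC <- length(barcodes)
  if (nrow(m) == nG && ncol(m) == nC) {
    # genes x cells: the 10x layout
  } else if (nrow(m) == nC && ncol(m) == nG) {
    m <- Matrix::t(m)
  } else {
    stop("matrix dimensions ", nrow(m), " x ", ncol(m),
         " match neither features (", nG, ") x barcodes (", nC,
         ") nor its transpose")
  }
  v <- m@x
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
    stop("matrix entries must be non-negative integers")
  }
  if (anyDuplicated(barcodes)) stop("duplicate cell barcodes")
  if (anyDuplicated(features[[1]])) stop("duplicate gene ids")
  m <- methods::as(m, "CsparseMatrix")
  dimnames(m) <- list(features[[1]], barcodes)
  rd <- S4Vectors::DataFrame(gene_id = features[[1]], row.names = features[[1]])
  rd$gene_name <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  if (ncol(features) >= 3) {
    rd$arm <- features[[3]]
    rd$class <- armToClass(features[[3]])
  }
  cd <- S4Vectors::DataFrame(barcode = barcodes, row.names = barcodes)
  truth <- file.path(dir, "truth.tsv")
  if (file.exists(truth)) {
    tr <- utils::read.table(truth, sep = "\t", header = TRUE)
    cd$true_cluster <- tr$cluster[match(barcodes, tr$barcode)]
    cd$true_rank <- tr$rank[match(barcodes, tr$barcode)]
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m), rowData = rd, colData = cd)
}

#' Write a 10x-style MatrixMarket triplet directory
#'
#' Emits `matrix.mtx` (genes x cells, `coordinate integer`, 1-based
#' indices), `features.tsv` (gene_id, gene_name, chromosome arm) and
#' `barcodes.tsv`. If the object carries ground truth
#' (`true_cluster`/`true_rank` in colData) a `truth.tsv` is written too.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write10x <- function(sce, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- methods::as(.counts(sce), "TsparseMatrix")
  con <- file(file.path(dir, "matrix.mtx"), "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(paste(nrow(m), ncol(m), length(m@x)), con)
  if (length(m@x)) {
    o <- order(m@j, m@i)  # column-major, the conventional MM ordering
    writeLines(paste(m@i[o] + 1L, m@j[o] + 1L,
                     format(m@x[o], scientific = FALSE, trim = TRUE)), con)
  }
  rd <- SummarizedExperiment::rowData(sce)
  arm <- if ("arm" %in% colnames(rd)) rd$arm else rep("UNKNOWN", nrow(sce))
  name <- if ("gene_name" %in% colnames(rd)) rd$gene_name else rownames(sce)
  utils::write.table(data.frame(rownames(sce), name, arm),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  cd <- SummarizedExperiment::colData(sce)
  if (all(c("true_cluster", "true_rank") %in% colnames(cd))) {
    utils::write.table(
      data.frame(barcode = colnames(sce), cluster = cd$true_cluster,
                 rank = cd$true_rank),
      file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(dir)
}

#' Read a gene-annotation TSV (gene_id, chromosome arm)
#'
#' Arm labels outside the known vocabulary (2R, 2L, 3R, 3L, X, Y, MT) map
#' to `UNKNOWN` with a warning. Duplicated gene ids are allowed only when
#' they agree on the arm; conflicting duplicates are an error.
#'
#' @param path two-column TSV, no header required (a header line whose
#'   first field is `gene_id` is skipped).
#' @return data.frame with columns `gene_id`, `arm`, `class`.
#' @export
readGeneAnnotation <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "")
  if (tab[1, 1] == "gene_id") tab <- tab[-1, , drop = FALSE]
  ids <- tab[[1]]
  arm <- tab[[2]]
  dup <- duplicated(ids)
  if (any(dup)) {
    agree <- tapply(arm, ids, function(a) length(unique(a)) == 1L)
    if (!all(agree)) {
      stop("conflicting arms for gene(s): ",
           paste(names(agree)[!agree], collapse = ", "))
    }
    ids <- ids[!dup]
    arm <- arm[!dup]
  }
  bad <- !(arm %in% .chromArms)
  if (any(bad)) {
    warning(sum(bad), " gene(s) with unrecognised arm label mapped to UNKNOWN")
    arm[bad] <- "UNKNOWN"
  }
  data.frame(gene_id = ids, arm = arm, class = armToClass(arm),
             row.names = NULL)
}

#' @keywords internal
.findFile <- function(dir, base) {
  for (f in file.path(dir, c(base, paste0(base, ".gz")))) {
    if (file.exists(f)) return(f)
  }
  stop("no ", base, "[.gz] in ", dir)
}

#' @keywords internal
.open <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path) else file(path)
}
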