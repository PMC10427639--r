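#' Depth-normalise and log-transform a count matrix
#'
#' Scales every cell to a common target total (the median cell depth by
#' default, mirroring standard count-depth normalisation), then applies
#' `log2(1 + x)` entrywise. Cells with zero total count cannot be scaled
#' and are dropped with a warning.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param target `"median"` (median cell depth) or `"fixed"`.
#' @param value the fixed target total when `target = "fixed"`.
#' @return the experiment with an added sparse `logcounts` assay.
#' @export
normalizeLog <- function(sce, target = c("median", "fixed"), value = NULL) {
  target <- match.arg(target)
  m <- .counts(sce)
  depth <- Matrix::colSums(m)
  if (any(depth == 0)) {
    warning(sum(depth == 0), " zero-total cell(s) dropped before normalisation")
    sce <- sce[, depth > 0]
    m <- .counts(sce)
    depth <- depth[depth > 0]
  }
  tgt <- if (target == "median") stats::median(depth) else {
    stopifnot(is.numeric(value), value > 0)
    value
  }
  norm <- m %*% Matrix::Diagonal(x = tgt / depth)
  norm <- methods::as(norm, "CsparseMatrix")
  norm@x <- log2(1 + norm@x)  # log2(1 + 0) = 0, so sparsity is preserved
  dimnames(norm) <- dimnames(m)
  SummarizedExperiment::assay(sce, "logcounts") <- norm
  sce
}

#' PCA embedding of cells on dispersion-ranked genes
#'
#' Ranks genes by dispersion (variance/mean of the log-normalised values),
#' keeps the top `nTopGenes`, centres them (and by default scales each
#' gene to unit variance, the convention of standard scRNA-seq PCA, so
#' highly expressed genes cannot dominate the components), and computes
#' principal components by exact eigendecomposition of the gene-gene
#' covariance. The sign of each component is fixed so that its
#' largest-magnitude gene loading is positive, making the embedding
#' deterministic.
#'
#' @param sce a `SingleCellExperiment` with a `logcounts` assay
#'   (see [normalizeLog()]).
#' @param nComponents number of components (default 10).
#' @param nTopGenes number of dispersion-ranked genes to use (default 1000;
#'   capped at the number of informative genes).
#' @param scaleGenes scale genes to unit variance before the
#'   decomposition (default TRUE).
#' @return an [Embedding-class] (cells x components scores).
#' @export
pcaEmbed <- function(sce, nComponents = 10L, nTopGenes = 1000L,
                     scaleGenes = TRUE) {
  stopifnot(nComponents >= 1)
  x <- .logcounts(sce)
  n <- ncol(x)
  mu <- Matrix::rowMeans(x)
  ex2 <- Matrix::rowMeans(x^2)
  v <- (ex2 - mu^2) * n / max(1, n - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  nTop <- min(nTopGenes, sum(disp > 0))
  top <- order(disp, decreasing = TRUE)[seq_len(nTop)]
  y <- as.matrix(Matrix::t(x[top, , drop = FALSE]))
  yc <- sweep(y, 2L, colMeans(y))
  if (scaleGenes) {
    sdv <- sqrt(colSums(yc^2) / max(1, n - 1))
    sdv[sdv == 0] <- 1
    yc <- sweep(yc, 2L, sdv, "/")
  }
  if (nComponents > min(n - 1L, nTop)) {
    stop("nComponents exceeds the rank of the centred data")
  }
  ee <- eigen(crossprod(yc) / max(1, n - 1), symmetric = TRUE)
  d <- nComponents
  rot <- ee$vectors[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) rot[, j] <- -rot[, j]
  }
  coords <- yc %*% rot
  rownames(coords) <- colnames(x)
  colnames(coords) <- paste0("PC", seq_len(d))
  methods::new("Embedding", coords = coords,
               explainedVariance = pmax(ee$values[seq_len(d)], 0),
               genes = rownames(x)[top])
}

# k-means++ seeding on a fixed, canonical row order; returns row indices
#' @keywords internal
.kmeansPP <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[centers[1L], ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) == 0) stop("k exceeds the number of distinct points")
    centers[j] <- sample.int(n, 1L, prob = d2)
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[centers[j], ])^2))
  }
  centers
}

#' K-means clustering of an embedding
#'
#' Lloyd iterations (via [stats::kmeans()]) from k-means++ seedings; the
#' best of `nInit` runs by total within-cluster sum of squares is kept.
#' Labels are renumbered by decreasing cluster size. Deterministic given
#' `seed`; cells are processed in a canonical data-derived order, so
#' permuting the input cells permutes the labels identically.
#'
#' @param embedding an [Embedding-class].
#' @param k number of clusters (`2 <= k <=` number of cells).
#' @param seed integer seed for the seeding draws.
#' @param nInit number of independent k-means++ restarts (default 10).
#' @return a [ClusterAssignment-class]; attributes `inertia` (best total
#'   within-SS) and `inertias` (all `nInit` runs) are attached.
#' @export
kmeansCluster <- function(embedding, k, seed = 1L, nInit = 10L) {
  x <- embeddingCoords(embedding)
  stopifnot(k >= 2, k <= nrow(x))
  if (k > nrow(unique(x))) stop("k exceeds the number of distinct points")
  ord <- do.call(order, as.data.frame(x))  # canonical, order-invariant
  xo <- x[ord, , drop = FALSE]
  runs <- .withSeed(seed, {
    lapply(seq_len(nInit), function(i) {
      ctr <- xo[.kmeansPP(xo, k), , drop = FALSE]
      suppressWarnings(
        stats::kmeans(xo, centers = ctr, iter.max = 100L,
                      algorithm = "Lloyd"))
    })
  })
  inertias <- vapply(runs, function(r) r$tot.withinss, numeric(1))
  best <- runs[[which.min(inertias)]]
  lab <- integer(nrow(x))
  lab[ord] <- best$cluster
  # renumber so cluster 1 is the largest
  sz <- tabulate(lab, nbins = k)
  remap <- integer(k)
  remap[order(-sz, seq_len(k))] <- seq_len(k)
  lab <- remap[lab]
  names(lab) <- rownames(x)
  res <- ClusterAssignment(lab, k = k)
  attr(res, "inertia") <- min(inertias)
  attr(res, "inertias") <- inertias
  res
}

#' Sweep k-means over a range of k
#'
#' @param embedding an [Embedding-class].
#' @param kRange integer vector of cluster counts (default `2:10`).
#' @param seed integer seed (each k gets its own derived stream).
#' @param nInit restarts per k.
#' @return named list (`"k2"`, `"k3"`, ...) of [ClusterAssignment-class].
#' @export
sweepK <- function(embedding, kRange = 2:10, seed = 1L, nInit = 10L) {
  res <- lapply(kRange, function(k) {
    kmeansCluster(embedding, k, seed = seed + k, nInit = nInit)
  })
  names(res) <- paste0("k", kRange)
  res
}
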