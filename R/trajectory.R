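#' Select the trajectory root cluster from a premeiotic marker
#'
#' Returns the cluster with maximal mean normalised expression of the
#' given marker gene (an automated stand-in for picking the root at the
#' visible peak of a premeiotic marker such as *vasa*). Ties are broken
#' toward the smallest label, with a warning.
#'
#' @param sce a `SingleCellExperiment`; `logcounts` is added via
#'   [normalizeLog()] if absent.
#' @param clusters a [ClusterAssignment-class].
#' @param rootMarker gene id present in the matrix.
#' @return integer cluster label.
#' @export
selectRoot <- function(sce, clusters, rootMarker) {
  if (!rootMarker %in% rownames(sce)) {
    stop("root marker '", rootMarker, "' absent from the matrix")
  }
  if (!"logcounts" %in% SummarizedExperiment::assayNames(sce)) {
    sce <- normalizeLog(sce)
  }
  x <- .logcounts(sce)[rootMarker, ]
  lab <- clusterLabels(clusters)[colnames(sce)]
  means <- tapply(x, lab, mean)
  means[is.na(means)] <- -Inf
  top <- which(means == max(means))
  if (length(top) > 1L) {
    warning("root marker expression tied across clusters; ",
            "picking the smallest label")
  }
  as.integer(names(means)[min(top)])
}

#' Centroid-MST pseudotime
#'
#' Builds the minimum spanning tree over cluster centroids in embedding
#' space (Euclidean distances) and assigns each cell the tree distance
#' from the root centroid to its cluster's centroid plus the cell's own
#' distance to that centroid, so within-cluster spread orders cells.
#' Pseudotime is shifted so its minimum over root-cluster cells is
#' exactly 0. This replaces learned principal-graph methods with a
#' deterministic, desk-scale ordering that is sufficient to sequence
#' clusters along a differentiation axis.
#'
#' @param embedding an [Embedding-class].
#' @param clusters a [ClusterAssignment-class] with >= 2 clusters.
#' @param root root cluster label (see [selectRoot()]).
#' @return a [TrajectoryResult-class].
#' @export
pseudotimeMST <- function(embedding, clusters, root) {
  x <- embeddingCoords(embedding)
  lab <- clusterLabels(clusters)[rownames(x)]
  k <- nlevels(lab)
  stopifnot(k >= 2, as.character(root) %in% levels(lab))
  cent <- t(vapply(levels(lab), function(l) {
    colMeans(x[lab == l, , drop = FALSE])
  }, numeric(ncol(x))))
  if (any(!is.finite(cent))) stop("empty cluster: centroid undefined")
  d <- as.matrix(stats::dist(cent))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  tree <- igraph::mst(g, weights = igraph::E(g)$weight)
  treeDist <- igraph::distances(tree, v = as.character(root),
                                weights = igraph::E(tree)$weight)[1L, ]
  ownDist <- sqrt(rowSums((x - cent[as.character(lab), , drop = FALSE])^2))
  pt <- treeDist[as.character(lab)] + ownDist
  pt <- pt - min(pt[lab == as.character(root)])
  pt <- pmax(pt, 0)
  names(pt) <- rownames(x)
  edges <- igraph::as_edgelist(tree)
  mode(edges) <- "integer"
  ord <- as.integer(levels(lab)[order(treeDist)])
  methods::new("TrajectoryResult", rootCluster = as.integer(root),
               clusterOrder = ord, pseudotime = pt, treeEdges = edges)
}
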