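# Independent oracles and small fixture builders shared across tests.

# Build a SingleCellExperiment from a dense genes x cells matrix.
makeSCE <- function(counts, arms = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  }
  rd <- S4Vectors::DataFrame(gene_id = rownames(counts),
                             row.names = rownames(counts))
  if (!is.null(arms)) {
    rd$arm <- arms
    rd$class <- armToClass(arms)
  }
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    rowData = rd,
    colData = S4Vectors::DataFrame(barcode = colnames(counts),
                                   row.names = colnames(counts)))
}

# Two-sided rank-sum p by full enumeration of all C(n1+n2, n1) group
# assignments (midranks used, so it also covers tied data).
enumRankSumP <- function(a, b) {
  n1 <- length(a)
  z <- c(a, b)
  r <- rank(z)
  obs <- sum(r[seq_len(n1)])
  splits <- utils::combn(length(z), n1)
  stats <- apply(splits, 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(stats <= obs), mean(stats >= obs)))
}

# Minimum spanning tree weight by exhaustive enumeration of all labelled
# trees on k nodes via Pruefer sequences (k <= 7 stays tiny).
bruteForceMSTWeight <- function(d) {
  k <- nrow(d)
  if (k == 2) return(d[1, 2])
  decode <- function(pruefer) {
    degree <- rep(1L, k)
    for (v in pruefer) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, nrow = k - 1, ncol = 2)
    ptr <- 1L
    for (v in pruefer) {
      leaf <- which(degree == 1L)[1L]
      edges[ptr, ] <- c(leaf, v)
      ptr <- ptr + 1L
      degree[leaf] <- degree[leaf] - 1L
      degree[v] <- degree[v] - 1L
    }
    last <- which(degree == 1L)
    edges[ptr, ] <- last
    edges
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(k)), k - 2)))
  best <- Inf
  for (i in seq_len(nrow(seqs))) {
    e <- decode(seqs[i, ])
    best <- min(best, sum(d[e]))
  }
  best
}

# Adjusted Rand index (mclust is the independent reference where heavier
# comparisons are needed; this local copy keeps light tests dependency-free).
ariOf <- function(a, b) mclust::adjustedRandIndex(a, b)
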