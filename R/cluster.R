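#' Shared-nearest-neighbour graph clustering
#'
#' Builds a k-nearest-neighbour graph (Euclidean distances in PC space,
#' neighbourhoods include the cell itself), re-weights edges by the Jaccard
#' similarity of the two cells' neighbour sets (shared-nearest-neighbour
#' weighting), prunes weak edges, and partitions the graph by
#' modularity-based Louvain community detection at the given resolution.
#' Labels are re-indexed so that cluster 0 is the largest.
#'
#' @param pcs cells x dimensions coordinate matrix with cell rownames.
#' @param k neighbourhood size (must be smaller than the number of cells).
#' @param resolution modularity resolution; larger values give more, smaller
#'   clusters.
#' @param seed integer seed (community detection is stochastic).
#' @param prune minimum Jaccard weight for an edge to be kept.
#' @return named integer vector of 0-based cluster labels (cell id ->
#'   label), with `k`, `resolution` and `seed` attached as attributes.
#' @examples
#' pts <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 8), 30))
#' rownames(pts) <- paste0("c", 1:60)
#' table(knnCluster(pts, k = 10, seed = 1))
#' @export
knnCluster <- function(pcs, k = 20, resolution = 0.5, seed = 0L,
                       prune = 1 / 15) {
  n <- nrow(pcs)
  if (k >= n) stop("k must be smaller than the number of cells")
  if (k < 1) stop("k must be positive")
  d <- as.matrix(dist(pcs))
  nb <- matrix(0L, n, k)
  for (i in seq_len(n)) nb[i, ] <- order(d[i, ])[seq_len(k)]
  ind <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nb),
                              x = 1, dims = c(n, n))
  shared <- as.matrix(Matrix::tcrossprod(ind))
  jac <- shared / (2 * k - shared)
  jac[jac < prune] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- unname(relabel[as.character(memb)])
  names(labels) <- rownames(pcs)
  attr(labels, "k") <- k
  attr(labels, "resolution") <- resolution
  attr(labels, "seed") <- seed
  labels
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Computes the rank-sum statistic of the first sample over the pooled
#' midranks. When both samples have at most `exactMax` observations the
#' two-sided p-value is obtained by exact enumeration of all group
#' assignments, counting assignments whose statistic is at least as far
#' from its null mean as the observed one (well-defined with ties).
#' Otherwise the normal approximation with the standard tie correction is
#' used (no continuity correction).
#'
#' @param x,y numeric samples.
#' @param exactMax largest group size for the exact path.
#' @return list with `statistic` (rank sum of `x`), `p` and `method`.
#' @export
rankSumTest <- function(x, y, exactMax = 10L) {
  nA <- length(x); nB <- length(y); n <- nA + nB
  if (nA < 1 || nB < 1) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nA)])
  mu <- nA * (n + 1) / 2
  if (nA <= exactMax && nB <= exactMax) {
    dev <- abs(W - mu)
    sums <- utils::combn(r, nA, FUN = sum)
    p <- mean(abs(sums - mu) >= dev - 1e-9)
    list(statistic = W, p = p, method = "exact")
  } else {
    ties <- table(r)
    tieTerm <- sum(ties^3 - ties)
    sigma2 <- nA * nB / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
    if (sigma2 <= 0) return(list(statistic = W, p = 1, method = "normal"))
    z <- (W - mu) / sqrt(sigma2)
    list(statistic = W, p = 2 * pnorm(-abs(z)), method = "normal")
  }
}

.lfcExpm1 <- function(vA, vB) {
  # natural-log fold change with a pseudocount of 1 in expm1 space
  log(mean(expm1(vA)) + 1) - log(mean(expm1(vB)) + 1)
}

#' Wilcoxon differential expression between two cell groups
#'
#' For every gene detected in at least `minDetectFrac` of either group, a
#' two-sided Wilcoxon rank-sum test ([rankSumTest()]) is run on the
#' log-normalised values and p-values are Benjamini-Hochberg adjusted over
#' the tested genes. The log fold change is computed in de-logged
#' (expm1) space with a pseudocount of 1:
#' `lfc = ln(mean(expm1(A)) + 1) - ln(mean(expm1(B)) + 1)`. Rows with
#' `adjusted_p <= alpha` and `|lfc| >= minAbsLFC` are returned, sorted by
#' adjusted p-value and then by absolute fold change (descending).
#'
#' @param x object carrying a `lognorm` assay, or a normalised matrix.
#' @param cellsA,cellsB disjoint barcode sets, each with at least 2 cells.
#' @param minDetectFrac detection fraction a gene must reach in at least
#'   one group to be tested.
#' @param alpha adjusted-p cutoff for retention.
#' @param minAbsLFC minimum absolute natural-log fold change.
#' @param exactMax exact-enumeration bound passed to [rankSumTest()].
#' @return data.frame with columns `gene_id`, `mean_A`, `mean_B`, `lfc`,
#'   `p_value`, `adjusted_p`, `direction`; the number of genes tested is
#'   attached as attribute `nTested`.
#' @export
wilcoxonDEG <- function(x, cellsA, cellsB, minDetectFrac = 0.1,
                        alpha = 0.05, minAbsLFC = 0.25, exactMax = 10L) {
  norm <- .getLogNorm(x)
  if (length(cellsA) < 2 || length(cellsB) < 2)
    stop("each group needs at least 2 cells")
  if (length(intersect(cellsA, cellsB)) > 0) stop("groups must be disjoint")
  missing <- setdiff(c(cellsA, cellsB), colnames(norm))
  if (length(missing) > 0)
    stop("unknown barcodes: ", paste(head(missing, 3), collapse = ", "))
  mA <- as.matrix(norm[, cellsA, drop = FALSE])
  mB <- as.matrix(norm[, cellsB, drop = FALSE])
  fracA <- rowMeans(mA > 0)
  fracB <- rowMeans(mB > 0)
  test <- which(pmax(fracA, fracB) >= minDetectFrac)
  if (length(test) == 0) {
    out <- data.frame(gene_id = character(), mean_A = numeric(),
                      mean_B = numeric(), lfc = numeric(),
                      p_value = numeric(), adjusted_p = numeric(),
                      direction = character())
    attr(out, "nTested") <- 0L
    return(out)
  }
  p <- numeric(length(test))
  lfc <- numeric(length(test))
  meanA <- numeric(length(test))
  meanB <- numeric(length(test))
  for (i in seq_along(test)) {
    g <- test[i]
    p[i] <- rankSumTest(mA[g, ], mB[g, ], exactMax = exactMax)$p
    meanA[i] <- mean(mA[g, ]); meanB[i] <- mean(mB[g, ])
    lfc[i] <- .lfcExpm1(mA[g, ], mB[g, ])
  }
  padj <- p.adjust(p, method = "BH")
  keep <- padj <= alpha & abs(lfc) >= minAbsLFC
  out <- data.frame(gene_id = rownames(norm)[test][keep],
                    mean_A = meanA[keep], mean_B = meanB[keep],
                    lfc = lfc[keep], p_value = p[keep],
                    adjusted_p = padj[keep],
                    direction = ifelse(lfc[keep] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$adjusted_p, -abs(out$lfc), out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nTested") <- length(test)
  out
}

#' One-vs-rest marker genes per cluster
#'
#' Runs [wilcoxonDEG()] for each cluster against all remaining cells and
#' keeps genes up-regulated in the cluster.
#'
#' @param x object carrying a `lognorm` assay, or a normalised matrix.
#' @param labels named cluster labels as returned by [knnCluster()].
#' @param ... passed to [wilcoxonDEG()].
#' @return named list (one element per cluster label) of marker tables;
#'   empty list when there is a single cluster.
#' @export
clusterMarkers <- function(x, labels, ...) {
  norm <- .getLogNorm(x)
  labs <- sort(unique(labels))
  if (length(labs) < 2) return(list())
  out <- list()
  for (l in labs) {
    inC <- names(labels)[labels == l]
    rest <- names(labels)[labels != l]
    if (length(inC) < 2 || length(rest) < 2) next
    tab <- wilcoxonDEG(norm, inC, rest, ...)
    out[[as.character(l)]] <- tab[tab$direction == "up", , drop = FALSE]
  }
  out
}

#' Ward (ward.D2) hierarchical clustering of cells
#'
#' Euclidean distances between cells over the selected marker-gene
#' submatrix, clustered agglomeratively under Ward's minimum-variance
#' criterion in its squared-distance (ward.D2) form. Used to order cells of
#' selected clusters along marker panels for dendrogram/heatmap displays.
#'
#' @param x object carrying a `lognorm` assay, or a normalised matrix.
#' @param cells optional barcodes to include (default all).
#' @param genes optional gene ids to include (default all).
#' @return an object of class `hclust` (merge heights are non-decreasing;
#'   `n - 1` merges for `n` cells).
#' @seealso [linkageToNewick()]
#' @export
wardHierarchy <- function(x, cells = NULL, genes = NULL) {
  norm <- .getLogNorm(x)
  if (!is.null(genes)) norm <- norm[genes, , drop = FALSE]
  if (!is.null(cells)) norm <- norm[, cells, drop = FALSE]
  if (ncol(norm) < 2) stop("need at least 2 cells")
  m <- t(as.matrix(norm))
  hclust(dist(m), method = "ward.D2")
}

#' Serialise a cell dendrogram as a Newick string
#'
#' @param hc an `hclust` object, e.g. from [wardHierarchy()].
#' @return single character Newick string with merge heights as branch
#'   lengths.
#' @export
linkageToNewick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc))
}

#' Iterative DEG-exclusion re-clustering
#'
#' Detects and removes the clustering artifact in which two large clusters
#' of the same tissue (here: the ectoderm) are split apart by genes that
#' are expressed ubiquitously and at high levels rather than by genuine
#' identity genes. Each pass runs the standard pipeline (log-normalise,
#' variable genes, PCA, SNN clustering), then looks for a candidate
#' spurious pair: the two largest clusters whose centroid profiles over a
#' supplied polarity-marker panel are nearly parallel (cosine similarity
#' above `cosineThreshold`), i.e. clusters that exhibit the same radial
#' polarity and therefore should not be separate tissues. Differentially
#' expressed genes between the pair are identified with [wilcoxonDEG()];
#' if that DEG set is dominated by highly expressed genes (its median
#' per-gene total raw count exceeds the `highExprQuantile` quantile of all
#' working genes), the DEGs are removed from the working gene set and the
#' loop repeats. It stops when no qualifying pair remains, the dominance
#' check fails, or `maxIter` exclusion rounds have run.
#'
#' @param sce a [SingleCellExperiment::SingleCellExperiment] with counts.
#' @param polarityGenes gene ids of the radial polarity panel used by the
#'   spurious-pair detector (e.g. [polarityPanelGenes()]).
#' @param pair optional explicit cluster pair (length-2 integer vector) to
#'   use in the first pass instead of the automatic detector.
#' @param scaleFactor passed to [logNormalize()].
#' @param nVarGenes number of variable genes per pass.
#' @param nPcs,k,resolution clustering parameters per pass.
#' @param minClusterFrac smallest cluster size (fraction of cells)
#'   considered by the pair detector.
#' @param cosineThreshold centroid cosine similarity above which a cluster
#'   pair is considered a spurious split of one tissue.
#' @param highExprQuantile quantile of per-gene total counts that the DEG
#'   median must exceed for the exclusion to proceed.
#' @param maxIter maximum number of exclusion rounds.
#' @param degParams list of arguments for [wilcoxonDEG()].
#' @param seed integer seed; per-pass seeds are derived from it.
#' @return list with `labels` (final cluster assignment), `excluded`
#'   (gene ids removed), `iterations` (per-pass log), `pca` (final PCA) and
#'   `norm` (the log-normalised matrix).
#' @export
exclusionRecluster <- function(sce, polarityGenes, pair = NULL,
                               scaleFactor = 1e4, nVarGenes = 500,
                               nPcs = 20, k = 20, resolution = 0.5,
                               minClusterFrac = 0.05,
                               cosineThreshold = 0.9,
                               highExprQuantile = 0.8, maxIter = 3,
                               degParams = list(), seed = 0L) {
  counts <- .getCounts(sce)
  # a higher fold-change floor than the generic DEG default: the artifact
  # genes carry large offsets, while incidental composition differences
  # between the halves of a split tissue stay below it
  degParams <- utils::modifyList(
    list(minDetectFrac = 0.1, alpha = 0.05, minAbsLFC = 0.4), degParams)
  norm <- logNormalize(counts, scaleFactor)
  geneTotals <- Matrix::rowSums(counts)
  working <- rownames(counts)
  excluded <- character()
  iterations <- list()
  labels <- NULL
  pca <- NULL

  for (pass in seq_len(maxIter + 1L)) {
    vg <- selectVariableGenes(norm[working, , drop = FALSE],
                              nTop = min(nVarGenes, length(working)))
    pca <- scaleAndPCA(norm, vg, nPcs = min(nPcs, length(vg)))
    labels <- knnCluster(pca$coords, k = k, resolution = resolution,
                         seed = .stageSeed(seed, paste0("cluster", pass)))
    info <- list(pass = pass, nWorkingGenes = length(working),
                 nClusters = length(unique(labels)))

    candidate <- if (!is.null(pair) && pass == 1L) pair else
      .findSpuriousPair(norm, labels, intersect(polarityGenes, working),
                        minClusterFrac, cosineThreshold)
    if (is.null(candidate)) {
      info$stop <- "no qualifying cluster pair"
      iterations[[pass]] <- info
      break
    }
    info$pair <- candidate
    cellsA <- names(labels)[labels == candidate[1]]
    cellsB <- names(labels)[labels == candidate[2]]
    deg <- do.call(wilcoxonDEG,
                   c(list(norm[working, , drop = FALSE], cellsA, cellsB),
                     degParams))
    info$nDEG <- nrow(deg)
    if (nrow(deg) == 0) {
      info$stop <- "no DEGs between candidate pair"
      iterations[[pass]] <- info
      break
    }
    cutoff <- quantile(geneTotals[working], highExprQuantile)
    degMedian <- median(geneTotals[deg$gene_id])
    info$degMedianTotal <- unname(degMedian)
    info$highExprCutoff <- unname(cutoff)
    if (degMedian <= cutoff) {
      info$stop <- "DEG set not dominated by high-expression genes"
      iterations[[pass]] <- info
      break
    }
    if (pass > maxIter) {
      info$stop <- "maxIter reached"
      iterations[[pass]] <- info
      break
    }
    excluded <- c(excluded, deg$gene_id)
    working <- setdiff(working, deg$gene_id)
    info$excluded <- deg$gene_id
    iterations[[pass]] <- info
  }
  list(labels = labels, excluded = excluded, iterations = iterations,
       pca = pca, norm = norm)
}

# Pick the largest cluster pair whose centroid polarity profiles are
# near-parallel; NULL when no pair qualifies.
.findSpuriousPair <- function(norm, labels, polarityGenes, minClusterFrac,
                              cosineThreshold) {
  if (length(polarityGenes) == 0) return(NULL)
  sizes <- table(labels)
  big <- as.integer(names(sizes)[sizes >= minClusterFrac * length(labels)])
  if (length(big) < 2) return(NULL)
  profiles <- vapply(big, function(l) {
    rowMeans(as.matrix(norm[polarityGenes,
                            names(labels)[labels == l], drop = FALSE]))
  }, numeric(length(polarityGenes)))
  pairs <- utils::combn(seq_along(big), 2)
  sizeSum <- sizes[as.character(big[pairs[1, ]])] +
    sizes[as.character(big[pairs[2, ]])]
  for (idx in order(-sizeSum)) {
    i <- pairs[1, idx]; j <- pairs[2, idx]
    # cosine of mean-centred profiles (= Pearson correlation): profiles of
    # expression panels are all-positive, so the raw cosine is high even
    # between distinct tissues; centring makes "similarly polarised"
    # discriminative
    if (.cosine(profiles[, i] - mean(profiles[, i]),
                profiles[, j] - mean(profiles[, j])) >= cosineThreshold)
      return(c(big[i], big[j]))
  }
  NULL
}
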