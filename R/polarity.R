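#' 2D embedding of cells
#'
#' Either the first two principal components verbatim (`pc12`, fully
#' deterministic and therefore the default for quantitative work) or a
#' nonlinear neighbour-graph manifold embedding (`nonlinear`; UMAP via the
#' uwot package when available, otherwise a seeded Fruchterman-Reingold
#' layout of the SNN graph). Both contracts are deterministic given the
#' seed and preserve the separation of well-separated groups.
#'
#' @param pcs cells x dimensions coordinate matrix with cell rownames.
#' @param method `"pc12"` or `"nonlinear"`.
#' @param seed integer seed (nonlinear method only).
#' @param nNeighbors neighbourhood size for the nonlinear method.
#' @return cells x 2 coordinate matrix with attributes `method` and `seed`.
#' @export
embed2D <- function(pcs, method = c("pc12", "nonlinear"), seed = 0L,
                    nNeighbors = 15L) {
  method <- match.arg(method)
  if (nrow(pcs) < 3) stop("need at least 3 cells to embed")
  if (method == "pc12") {
    if (ncol(pcs) < 2) stop("pc12 embedding needs at least 2 dimensions")
    coords <- pcs[, 1:2, drop = FALSE]
  } else if (requireNamespace("uwot", quietly = TRUE)) {
    set.seed(seed)
    coords <- uwot::umap(pcs, n_neighbors = min(nNeighbors, nrow(pcs) - 1),
                         n_threads = 1, n_sgd_threads = 0)
    rownames(coords) <- rownames(pcs)
  } else {
    k <- min(nNeighbors, nrow(pcs) - 1)
    d <- as.matrix(dist(pcs))
    nb <- t(apply(d, 1, function(r) order(r)[2:(k + 1)]))
    g <- igraph::graph_from_edgelist(
      cbind(rep(seq_len(nrow(pcs)), k), as.vector(nb)), directed = FALSE)
    g <- igraph::simplify(g)
    set.seed(seed)
    coords <- igraph::layout_with_fr(g)
    rownames(coords) <- rownames(pcs)
  }
  colnames(coords) <- c("dim1", "dim2")
  attr(coords, "method") <- method
  attr(coords, "seed") <- seed
  coords
}

#' Reconstructed polarity axis of a cell subset
#'
#' The axis is the first principal axis of the subset's embedding points:
#' cells are projected onto the direction of maximal variance, which for a
#' radially polarised epithelial sheet recovers the peripheral-to-central
#' (future anterior-posterior) order. The axis sign follows the convention
#' that the largest-magnitude loading is positive; since the true
#' orientation is not identifiable from dissociated cells, downstream
#' agreement statistics use absolute correlations.
#'
#' @param emb cells x 2 embedding from [embed2D()].
#' @param subset optional barcodes to evaluate (default: all cells).
#' @return named numeric vector of axis coordinates for the subset.
#' @export
polarityAxis <- function(emb, subset = NULL) {
  pts <- if (is.null(subset)) emb else emb[subset, , drop = FALSE]
  if (nrow(pts) < 3) stop("subset must contain at least 3 cells")
  centered <- sweep(pts, 2, colMeans(pts))
  if (all(abs(centered) < 1e-12)) {
    warning("all points coincide; returning a zero axis")
    return(setNames(numeric(nrow(pts)), rownames(pts)))
  }
  sv <- svd(centered, nu = 1, nv = 1)
  v <- sv$v[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  setNames(as.numeric(centered %*% v), rownames(pts))
}

#' Score a reconstructed axis against the true radial position
#'
#' Computes the absolute Spearman correlation between the per-cell axis
#' coordinate and the true radius over the evaluated cells and, when a
#' cluster assignment is supplied, the absolute Kendall tau between the
#' order of cluster centroids along the axis and the order of cluster mean
#' true radii (restricted to clusters with at least `minClusterSize`
#' evaluated cells).
#'
#' @param axis named axis coordinates from [polarityAxis()].
#' @param truth truth table covering the axis cells ([sampleDiscCells()]).
#' @param assignment optional named cluster labels ([knnCluster()]).
#' @param minClusterSize smallest cluster entering the tau statistic.
#' @param subset free-text description of the evaluated subset.
#' @return a [PolarityReport].
#' @export
polarityScore <- function(axis, truth, assignment = NULL,
                          minClusterSize = 5L, subset = "all cells") {
  if (length(axis) < 3) stop("need at least 3 cells to score")
  idx <- match(names(axis), truth$cell_id)
  if (anyNA(idx)) stop("axis contains cells absent from the truth table")
  radius <- truth$radius[idx]
  sp <- abs(cor(axis, radius, method = "spearman"))
  tau <- NA_real_
  if (!is.null(assignment)) {
    labs <- assignment[names(axis)]
    tab <- table(labs)
    use <- names(tab)[tab >= minClusterSize]
    if (length(use) >= 2) {
      centro <- vapply(use, function(l) mean(axis[labs == l]), numeric(1))
      meanR <- vapply(use, function(l) mean(radius[labs == l]), numeric(1))
      tau <- abs(cor(centro, meanR, method = "kendall"))
    }
  }
  new("PolarityReport", axis = axis, spearmanAbs = sp,
      clusterOrderTau = tau, subset = subset)
}
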