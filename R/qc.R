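#' Mode of a per-cell total-count distribution
#'
#' Estimates the mode of the library-size distribution as the centre of the
#' most populated fixed-width histogram bin (bins `[k*w, (k+1)*w)`), with
#' ties broken toward the lower bin. This is the reference point of the
#' mode-relative molecule filter, which keeps cells within a configurable
#' percentage band around the mode (default 50%-200%).
#'
#' @param totals per-cell total molecule counts (positive).
#' @param binWidth histogram bin width in molecules.
#' @return the centre of the most populated bin (a positive number).
#' @examples
#' depthMode(c(10, 10, 10, 90, 90), binWidth = 20)  # 10
#' @export
depthMode <- function(totals, binWidth = 100) {
  if (length(totals) == 0) stop("totals must be non-empty")
  if (binWidth <= 0) stop("binWidth must be positive")
  bins <- floor(totals / binWidth)
  tab <- table(bins)
  best <- as.numeric(names(tab)[which.max(tab)])  # which.max: first = lowest
  (best + 0.5) * binWidth
}

#' Quality-control thresholds
#'
#' Two filtering rules are supported. The `absolute` rule keeps cells with
#' `minGenes <= detected genes <= maxGenes` and total molecules strictly
#' below `maxMolecules` (the strict inequality follows the usual
#' "less than N molecules" phrasing of such filters). The `mode_relative`
#' rule keeps cells whose total molecule count lies within
#' `[lowerFrac, upperFrac]` times the mode of the library-size
#' distribution (see [depthMode()]); the defaults 0.5 and 2.0 implement a
#' 50%-200%-of-mode band.
#'
#' @param kind `"absolute"` or `"mode_relative"`.
#' @param minGenes,maxGenes detected-gene bounds (absolute rule).
#' @param maxMolecules strict upper bound on total molecules (absolute
#'   rule).
#' @param lowerFrac,upperFrac multiples of the mode (mode-relative rule).
#' @param binWidth histogram bin width used for the mode.
#' @return a `QCThresholds` list.
#' @export
qcThresholds <- function(kind = c("absolute", "mode_relative"),
                         minGenes = 200L, maxGenes = Inf,
                         maxMolecules = Inf, lowerFrac = 0.5,
                         upperFrac = 2.0, binWidth = 100L) {
  kind <- match.arg(kind)
  if (minGenes > maxGenes) stop("minGenes must not exceed maxGenes")
  if (!(lowerFrac > 0 && lowerFrac < upperFrac))
    stop("need 0 < lowerFrac < upperFrac")
  structure(list(kind = kind, minGenes = minGenes, maxGenes = maxGenes,
                 maxMolecules = maxMolecules, lowerFrac = lowerFrac,
                 upperFrac = upperFrac, binWidth = binWidth),
            class = "QCThresholds")
}

#' Filter cells on detected genes and total molecules
#'
#' Removes low-complexity cells and potential doublets using either an
#' absolute window on detected genes plus a molecule ceiling, or a
#' mode-relative molecule band (see [qcThresholds()]). The gene set is
#' never changed. A report describing the decision (rule, thresholds,
#' computed mode, kept/removed counts) is returned and, for
#' SingleCellExperiment input, also stored in the object metadata under
#' `qcReport`.
#'
#' @param x a [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay, or a genes x cells count matrix.
#' @param thresholds a [qcThresholds()] object.
#' @return the filtered object, with the QC report in `metadata(x)$qcReport`
#'   (or as attribute `qcReport` for matrix input).
#' @examples
#' sce <- simulateGermDisc(150, panel = defaultPanel(nUbiquitous = 10,
#'                                                   nNoise = 20), seed = 1)
#' filtered <- qcFilter(sce, qcThresholds("mode_relative"))
#' S4Vectors::metadata(filtered)$qcReport$nKept
#' @export
qcFilter <- function(x, thresholds = qcThresholds()) {
  counts <- .getCounts(x)
  totals <- Matrix::colSums(counts)
  nGenes <- Matrix::colSums(counts > 0)
  if (thresholds$kind == "absolute") {
    keep <- nGenes >= thresholds$minGenes & nGenes <= thresholds$maxGenes &
      totals < thresholds$maxMolecules
    mode <- NA_real_
  } else {
    mode <- depthMode(totals[totals > 0], thresholds$binWidth)
    keep <- totals >= thresholds$lowerFrac * mode &
      totals <= thresholds$upperFrac * mode
  }
  if (!any(keep))
    warning("QC filter removed every cell; returning an empty matrix")
  report <- list(kind = thresholds$kind, thresholds = unclass(thresholds),
                 depthMode = mode, nInput = ncol(counts),
                 nKept = sum(keep), nRemoved = sum(!keep),
                 removed = colnames(counts)[!keep])
  if (is(x, "SummarizedExperiment")) {
    out <- x[, keep]
    S4Vectors::metadata(out)$qcReport <- report
  } else {
    out <- counts[, keep, drop = FALSE]
    attr(out, "qcReport") <- report
  }
  out
}

#' Log-normalise a count matrix
#'
#' Per-cell depth normalisation followed by a log transform:
#' `value(g, c) = ln(1 + count(g, c) * scaleFactor / total(c))`. Cells with
#' zero total counts yield all-zero columns and trigger a warning.
#'
#' @param x a [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay, or a genes x cells count matrix.
#' @param scaleFactor per-cell target molecule total (default 10,000).
#' @return for SingleCellExperiment input, the object with a new `lognorm`
#'   assay; for matrix input, the normalised matrix.
#' @export
logNormalize <- function(x, scaleFactor = 1e4) {
  counts <- .getCounts(x)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (scaleFactor <= 0) stop("scaleFactor must be positive")
  totals <- Matrix::colSums(counts)
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total counts left all-zero")
    totals[zero] <- 1
  }
  norm <- log1p(.scaleCols(counts, scaleFactor / totals))
  dimnames(norm) <- dimnames(counts)
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "lognorm") <- norm
    x
  } else {
    norm
  }
}

#' Rank genes by standardised dispersion and pick the most variable
#'
#' Genes are binned (default 20 bins) by mean normalised expression; within
#' each bin the dispersion (variance / mean) is z-scored, which removes the
#' mean-dispersion trend, and genes are ranked by this standardised
#' dispersion. Returns the top `nTop` gene ids.
#'
#' @param x object carrying a `lognorm` assay, or a normalised matrix.
#' @param nTop number of genes to return (at most the number of genes).
#' @param nBins number of mean-expression bins.
#' @return character vector of `nTop` gene ids, most variable first.
#' @export
selectVariableGenes <- function(x, nTop = 2000, nBins = 20) {
  norm <- .getLogNorm(x)
  if (nTop > nrow(norm)) stop("nTop exceeds the number of genes")
  means <- Matrix::rowMeans(norm)
  # E[x^2] - E[x]^2 with the small-sample correction, sparse-safe
  ex2 <- Matrix::rowMeans(norm^2)
  n <- ncol(norm)
  vars <- (ex2 - means^2) * n / max(1, n - 1)
  if (all(vars < .Machine$double.eps)) {
    warning("all genes are constant; returning genes in input order")
    return(rownames(norm)[seq_len(nTop)])
  }
  disp <- ifelse(means > 0, vars / means, 0)
  bin <- cut(means, breaks = nBins, labels = FALSE, include.lowest = TRUE)
  gmu <- mean(disp); gsd <- sd(disp)
  z <- if (gsd > 0) (disp - gmu) / gsd else disp * 0
  for (b in unique(bin)) {
    i <- which(bin == b)
    mu <- mean(disp[i]); s <- sd(disp[i])
    # singleton or constant bins keep the global z-score fallback
    if (!is.na(s) && s > 0) z[i] <- (disp[i] - mu) / s
  }
  rownames(norm)[order(z, decreasing = TRUE)][seq_len(nTop)]
}

#' Scale genes and compute principal components
#'
#' Each selected gene is centred to mean 0 and scaled to unit variance
#' across cells (zero-variance genes are dropped), scaled values are
#' clipped to `[-clip, clip]`, and principal components are obtained from
#' the singular value decomposition of the cells x genes matrix. The sign
#' of each component is fixed so that its largest-magnitude gene loading is
#' positive, making results reproducible across platforms and invariant to
#' cell order.
#'
#' @param x object carrying a `lognorm` assay, or a normalised matrix.
#' @param genes gene ids to use (e.g. from [selectVariableGenes()]).
#' @param nPcs number of components (at most `min(nCells, nGenes)`).
#' @param clip clipping bound for scaled values.
#' @param randomized logical; use a seeded randomised subspace solver
#'   instead of the exact SVD (useful for very large matrices; the default
#'   exact path is fully deterministic).
#' @param seed seed for the randomised solver.
#' @return a list with `coords` (cells x nPcs matrix), `varExplained`
#'   (fraction of variance per component, non-increasing), `rotation`
#'   (gene loadings) and `genes` (genes actually used).
#' @export
scaleAndPCA <- function(x, genes, nPcs = 20, clip = 10, randomized = FALSE,
                        seed = 0L) {
  norm <- .getLogNorm(x)
  missing <- setdiff(genes, rownames(norm))
  if (length(missing) > 0)
    stop("genes not present in matrix: ", paste(head(missing, 3),
                                                collapse = ", "))
  m <- as.matrix(norm[genes, , drop = FALSE])
  sds <- apply(m, 1L, sd)
  keep <- sds > 0
  if (!all(keep)) {
    message("dropping ", sum(!keep), " zero-variance gene(s) before PCA")
    m <- m[keep, , drop = FALSE]
    sds <- sds[keep]
  }
  if (nrow(m) == 0L) stop("no gene with non-zero variance")
  scaled <- (m - rowMeans(m)) / sds
  scaled[scaled > clip] <- clip
  scaled[scaled < -clip] <- -clip
  X <- t(scaled)                    # cells x genes
  maxPcs <- min(dim(X))
  if (nPcs > maxPcs)
    stop("nPcs (", nPcs, ") exceeds min(nCells, nGenes) = ", maxPcs)
  if (randomized) {
    set.seed(seed)
    # subspace iteration on a Gaussian sketch
    k <- min(maxPcs, nPcs + 10L)
    Omega <- matrix(rnorm(ncol(X) * k), ncol(X), k)
    Q <- qr.Q(qr(X %*% Omega))
    for (i in 1:2) Q <- qr.Q(qr(X %*% crossprod(X, Q)))
    sv <- svd(crossprod(Q, X), nu = nPcs, nv = nPcs)
    u <- Q %*% sv$u
    d <- sv$d
  } else {
    sv <- svd(X, nu = nPcs, nv = nPcs)
    u <- sv$u
    d <- sv$d
  }
  v <- sv$v
  for (j in seq_len(nPcs)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  coords <- u %*% diag(d[seq_len(nPcs)], nPcs)
  rownames(coords) <- colnames(norm)
  colnames(coords) <- paste0("PC", seq_len(nPcs))
  rownames(v) <- rownames(m)
  list(coords = coords,
       varExplained = d[seq_len(nPcs)]^2 / sum(d^2),
       rotation = v[, seq_len(nPcs), drop = FALSE],
       genes = rownames(m))
}
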