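# Internal helpers shared across modules.

# Extract a counts matrix from either a SingleCellExperiment-like object or
# a plain (sparse) matrix. Returns a dgCMatrix or base matrix unchanged.
.getCounts <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "counts")
  } else {
    x
  }
}

# Extract a normalised matrix: for a SummarizedExperiment, assay "lognorm";
# for a plain matrix, the matrix itself.
.getLogNorm <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    if (!"lognorm" %in% SummarizedExperiment::assayNames(x))
      stop("no 'lognorm' assay; run logNormalize() first")
    SummarizedExperiment::assay(x, "lognorm")
  } else {
    x
  }
}

.checkCountMatrix <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("count matrix must carry gene rownames and cell colnames")
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(m))) stop("duplicate cell barcodes")
  if (any(m < 0)) stop("counts must be non-negative")
  invisible(TRUE)
}

# Deterministic per-stage seed derived from a global seed; stays within
# 32-bit integer range.
.stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

.cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# logistic function used for fuzzy radial expression boundaries
.sigmoid <- function(z) 1 / (1 + exp(-z))

# Column-wise scaling of a sparse or dense genes x cells matrix by per-cell
# factors (multiplies column j by f[j]) without densifying.
.scaleCols <- function(m, f) {
  if (is(m, "sparseMatrix")) {
    m %*% Matrix::Diagonal(x = f)
  } else {
    sweep(m, 2L, f, "*")
  }
}
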