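.SCHEMA_VERSION <- "1.0"

#' Write a count matrix as Matrix Market triplets
#'
#' Writes `matrix.mtx` (1-based coordinate format), `features.tsv` (gene
#' ids) and `barcodes.tsv` into a directory. For SingleCellExperiment
#' input the cell truth table (`truth.tsv`), the gene panel
#' (`panel.tsv`) and a provenance JSON are written alongside.
#'
#' @param x a [SingleCellExperiment::SingleCellExperiment] or a genes x
#'   cells count matrix.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCounts <- function(x, dir) {
  counts <- .getCounts(x)
  .checkCountMatrix(counts)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(as(counts, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  if (is(x, "SummarizedExperiment")) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    utils::write.table(cd, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    rd <- as.data.frame(SummarizedExperiment::rowData(x))
    utils::write.table(rd, file.path(dir, "panel.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    prov <- S4Vectors::metadata(x)$provenance
    if (!is.null(prov)) {
      prov$schema_version <- .SCHEMA_VERSION
      jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(dir)
}

#' Read a count matrix
#'
#' Reads either a Matrix Market triplet directory (`matrix.mtx` +
#' `features.tsv` + `barcodes.tsv`, cellranger-style; 1-based file indices
#' are handled by the reader) or a dense TSV with gene ids in the first
#' column and barcodes in the header. A truth table (`truth.tsv`), if
#' present in a triplet directory, is attached as column data.
#'
#' @param path directory (mtx_triplet) or file (dense_tsv).
#' @param format `"mtx_triplet"` or `"dense_tsv"`.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay.
#' @export
readCounts <- function(path, format = c("mtx_triplet", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    mtx <- file.path(path, "matrix.mtx")
    feat <- file.path(path, "features.tsv")
    bc <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, feat, bc))
      if (!file.exists(f)) stop("missing file: ", f)
    m <- as(Matrix::readMM(mtx), "CsparseMatrix")
    genes <- readLines(feat)
    cells <- readLines(bc)
    if (nrow(m) != length(genes))
      stop("dimension mismatch: ", mtx, " declares ", nrow(m),
           " genes but ", feat, " has ", length(genes), " lines")
    if (ncol(m) != length(cells))
      stop("dimension mismatch: ", mtx, " declares ", ncol(m),
           " cells but ", bc, " has ", length(cells), " lines")
    dimnames(m) <- list(genes, cells)
    cd <- S4Vectors::DataFrame(cell_id = cells, row.names = cells)
    truthFile <- file.path(path, "truth.tsv")
    if (file.exists(truthFile)) {
      tr <- utils::read.delim(truthFile, stringsAsFactors = FALSE)
      if (all(cells %in% tr$cell_id))
        cd <- S4Vectors::DataFrame(tr[match(cells, tr$cell_id), ],
                                   row.names = cells)
    }
    SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = m), colData = cd)
  } else {
    if (!file.exists(path)) stop("missing file: ", path)
    tab <- utils::read.delim(path, row.names = 1, check.names = FALSE)
    m <- as(as.matrix(tab), "CsparseMatrix")
    .checkCountMatrix(m)
    SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = m),
      colData = S4Vectors::DataFrame(cell_id = colnames(m),
                                     row.names = colnames(m)))
  }
}

#' Pipeline run configuration
#'
#' Bundles per-stage parameter blocks and a global seed. Every stochastic
#' stage derives its own seed deterministically from the global seed and
#' the stage name, so a configuration fully determines a run. The
#' configuration round-trips through YAML unchanged.
#'
#' @param seed global integer seed.
#' @param simulate,qc,normalize,cluster,embed,polarity,search,markers
#'   named lists overriding stage defaults.
#' @return a `RunConfig` list.
#' @export
runConfig <- function(seed = 1L, simulate = list(), qc = list(),
                      normalize = list(), cluster = list(), embed = list(),
                      polarity = list(), search = list(), markers = list()) {
  defaults <- list(
    seed = as.integer(seed),
    simulate = list(nCells = 2000L, modality = "cell"),
    qc = list(kind = "mode_relative", lowerFrac = 0.5, upperFrac = 2.0,
              binWidth = 100L),
    normalize = list(scaleFactor = 1e4),
    cluster = list(nVarGenes = 500L, nPcs = 20L, k = 20L, resolution = 0.5,
                   cosineThreshold = 0.9, highExprQuantile = 0.8,
                   maxIter = 3L),
    embed = list(method = "pc12"),
    polarity = list(minClusterSize = 5L),
    search = list(width = 128L, height = 128L, splatRadius = 2L),
    markers = list(exprThreshold = 2, maxDetectedCells = 20L))
  user <- list(simulate = simulate, qc = qc, normalize = normalize,
               cluster = cluster, embed = embed, polarity = polarity,
               search = search, markers = markers)
  for (stage in names(user))
    defaults[[stage]] <- utils::modifyList(defaults[[stage]], user[[stage]])
  structure(defaults, class = "RunConfig")
}

#' @rdname runConfig
#' @param path YAML file path.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(runConfig, c(list(seed = raw$seed),
                       raw[setdiff(names(raw), "seed")]))
}

#' @rdname runConfig
#' @param config a `RunConfig`.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full germ-disc reconstruction pipeline
#'
#' Executes simulation (or reads supplied counts), quality control,
#' normalisation, the DEG-exclusion re-clustering loop, 2D embedding,
#' polarity-axis reconstruction and scoring on ectodermal cells, the
#' rare-cell marker filter (targeting a CM cell when ground truth is
#' available) and the template-matching similarity search (seeded from a
#' cumulus marker when ground truth is available). All tables, reports and
#' a provenance JSON recording every derived seed are written to the
#' output directory; re-running the same configuration reproduces the
#' outputs bit-identically.
#'
#' @param config a [runConfig()].
#' @param outDir output directory.
#' @param sce optional pre-made [SingleCellExperiment::SingleCellExperiment]
#'   (skips the simulation stage).
#' @return invisibly, a list with the main in-memory results
#'   (`sce`, `exclusion`, `embedding`, `polarity`, `rareMarkers`, `hits`,
#'   `provenance`).
#' @export
runPipeline <- function(config = runConfig(), outDir, sce = NULL) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seeds <- list()
  takeSeed <- function(stage) {
    s <- .stageSeed(config$seed, stage)
    seeds[[stage]] <<- s
    s
  }

  if (is.null(sce)) {
    sce <- simulateGermDisc(nCells = config$simulate$nCells,
                            modality = config$simulate$modality,
                            seed = takeSeed("simulate"))
  }
  truth <- cellTruth(sce)
  panel <- genePanel(sce)

  thr <- do.call(qcThresholds, config$qc)
  sce <- qcFilter(sce, thr)
  qcReport <- S4Vectors::metadata(sce)$qcReport
  qcReport$schema_version <- .SCHEMA_VERSION
  jsonlite::write_json(qcReport, file.path(outDir, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA)

  polGenes <- polarityPanelGenes(panel)
  excl <- do.call(exclusionRecluster,
                  c(list(sce, polarityGenes = polGenes,
                         scaleFactor = config$normalize$scaleFactor,
                         seed = takeSeed("cluster")),
                    config$cluster[c("nVarGenes", "nPcs", "k", "resolution",
                                     "cosineThreshold", "highExprQuantile",
                                     "maxIter")]))
  utils::write.table(
    data.frame(cell_id = names(excl$labels), cluster = excl$labels),
    file.path(outDir, "assignment.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeLines(excl$excluded, file.path(outDir, "excluded_genes.txt"))
  jsonlite::write_json(
    list(schema_version = .SCHEMA_VERSION, iterations = excl$iterations),
    file.path(outDir, "iteration_log.json"), auto_unbox = TRUE, digits = NA)

  emb <- embed2D(excl$pca$coords, method = config$embed$method,
                 seed = takeSeed("embed"))
  utils::write.table(
    data.frame(cell_id = rownames(emb), emb),
    file.path(outDir, "embedding.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  truthKept <- truth[truth$cell_id %in% colnames(sce), , drop = FALSE]
  ecto <- truthKept$cell_id[!is.na(truthKept$layer) &
                              truthKept$layer == "ectoderm"]
  polarity <- NULL
  if (length(ecto) >= 3) {
    # polarity is read off a PCA of the polarity-gene subspace
    polPCA <- scaleAndPCA(excl$norm, intersect(polGenes, rownames(sce)),
                          nPcs = 2)
    axis <- polarityAxis(embed2D(polPCA$coords, method = "pc12"), ecto)
    polarity <- polarityScore(axis, truthKept, excl$labels,
                              subset = "ectodermal cells")
    jsonlite::write_json(
      list(schema_version = .SCHEMA_VERSION,
           spearman_abs = spearmanAbs(polarity),
           cluster_order_tau = clusterOrderTau(polarity),
           subset = "ectodermal cells", n_cells = length(axis)),
      file.path(outDir, "polarity.json"), auto_unbox = TRUE, digits = NA)
  }

  rare <- NULL
  cmCells <- truthKept$cell_id[!is.na(truthKept$subtype) &
                                 truthKept$subtype == "CM"]
  if (length(cmCells) > 0) {
    rare <- rareCellMarkers(excl$norm, cmCells[1],
                            exprThreshold = config$markers$exprThreshold,
                            maxDetectedCells = config$markers$maxDetectedCells)
    utils::write.table(rare, file.path(outDir, "rare_markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  hits <- NULL
  cumGenes <- intersect(panel$gene_id[panel$klass == "rare_marker" &
                                        !is.na(panel$target) &
                                        panel$target == "cumulus"],
                        rownames(sce))
  if (length(cumGenes) > 0) {
    imgs <- rasterizePanel(emb, excl$norm,
                           width = config$search$width,
                           height = config$search$height,
                           splatRadius = config$search$splatRadius)
    q <- autoTemplateQuery(imgs, cumGenes[1])
    hits <- templateSearch(q, imgs)
    utils::write.table(hits, file.path(outDir, "template_hits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  prov <- list(schema_version = .SCHEMA_VERSION, config = unclass(config),
               seeds = seeds, nCellsKept = ncol(sce),
               excludedGenes = length(excl$excluded))
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(sce = sce, exclusion = excl, embedding = emb,
                 polarity = polarity, rareMarkers = rare, hits = hits,
                 provenance = prov))
}

#' Bounding-box template query for a gene's expression domain
#'
#' Builds a fixed-mode [templateQuery()] from the bounding box of the
#' pixels where the gene's image exceeds `level`, expanded by `pad`
#' pixels so the template includes expressing and neighbouring
#' non-expressing cells.
#'
#' @param images an [ExpressionImageSet].
#' @param gene query gene id.
#' @param level intensity defining the expression domain.
#' @param pad pixels of context around the bounding box.
#' @return a [templateQuery()].
#' @export
autoTemplateQuery <- function(images, gene, level = 0.3, pad = 6L) {
  img <- intensities(getImage(images, gene))
  on <- which(img > level, arr.ind = TRUE)
  if (nrow(on) == 0) stop("gene '", gene, "' has no pixel above ", level)
  H <- nrow(img); W <- ncol(img)
  y0 <- max(0L, min(on[, 1]) - 1L - pad)
  x0 <- max(0L, min(on[, 2]) - 1L - pad)
  y1 <- min(H, max(on[, 1]) + pad)
  x1 <- min(W, max(on[, 2]) + pad)
  templateQuery(gene, x0, y0, max(2L, x1 - x0), max(2L, y1 - y0),
                mode = "fixed")
}
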