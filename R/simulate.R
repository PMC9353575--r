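#' Default germ-disc geometry
#'
#' Geometry of the simulated late germ disc: a single-layered epithelial
#' disc whose centre corresponds to the future posterior pole and whose rim
#' corresponds to the future anterior. Cell positions are sampled uniformly
#' over the disc area; germ layers are assigned by radial position
#' (endoderm at the centre, mesoderm at the rim, ectoderm in between) and
#' rare subtypes are drawn from the eligible layer pools.
#'
#' @param centerCutoff radius below which cells are endodermal (in [0, 1]).
#' @param rimCutoff radius above which cells are mesodermal (rim cells that
#'   internalise from the disc periphery).
#' @param fracCM fraction of all cells that are cumulus mesenchymal (CM)
#'   cells; CM cells are part of the endoderm and sit near the disc centre.
#' @param fracCumulus fraction of cumulus cells (central endodermal cells
#'   responding to CM signals).
#' @param fracEmerging fraction of `emerging_posterior` cells: central
#'   endodermal cells in a nascent transcriptional state that is easier to
#'   detect in nuclear (pre-mRNA rich) profiles.
#' @param fracCaudal fraction of `caudal_mesoderm` cells within the
#'   mesodermal rim.
#' @param fracRimIntermediate fraction of rim cells in an
#'   ectoderm-to-mesoderm intermediate state; they sit just outside the rim
#'   cutoff and co-express ectodermal and mesodermal markers.
#' @param rimBand radial width of the band (starting at `rimCutoff`) from
#'   which rim-intermediate cells are drawn.
#' @param centralPocket radius below which CM and cumulus cells are drawn.
#' @return named list of geometry parameters.
#' @export
discGeometry <- function(centerCutoff = 0.45, rimCutoff = 0.85,
                         fracCM = 0.005, fracCumulus = 0.02,
                         fracEmerging = 0.05, fracCaudal = 0,
                         fracRimIntermediate = 0.02, rimBand = 0.06,
                         centralPocket = 0.25) {
  stopifnot(centerCutoff > 0, centerCutoff < rimCutoff,
            rimCutoff > 0, rimCutoff < 1)
  fr <- c(fracCM, fracCumulus, fracEmerging, fracCaudal, fracRimIntermediate)
  if (any(fr < 0) || sum(fr) > 1)
    stop("subtype fractions must be non-negative and sum to at most 1")
  list(centerCutoff = centerCutoff, rimCutoff = rimCutoff,
       fracCM = fracCM, fracCumulus = fracCumulus,
       fracEmerging = fracEmerging, fracCaudal = fracCaudal,
       fracRimIntermediate = fracRimIntermediate, rimBand = rimBand,
       centralPocket = centralPocket)
}

#' Sample ground-truth cells on the germ disc
#'
#' Positions are area-uniform over the unit disc (radius = sqrt(U)), so the
#' squared radius is Uniform(0, 1). Layers follow radial cutoffs: endoderm
#' below `centerCutoff`, mesoderm above `rimCutoff` (internalising rim
#' cells), ectoderm in between. Rare subtypes (CM, cumulus,
#' emerging_posterior, caudal_mesoderm, rim_intermediate) are sampled from
#' their eligible pools; CM and cumulus cells are endodermal and drawn from
#' the central pocket, and rim-intermediate cells have radius at or above
#' the rim cutoff. Each ectodermal cell is additionally assigned a random
#' artifact group (-0.5 or +0.5) used by `ubiquitous_deg` gene programs;
#' non-ectodermal cells receive the neutral value 0 so the artifact splits
#' only the ectoderm, and the symmetric coding keeps the expected library
#' size of the two halves equal.
#'
#' @param nCells number of cells (0 yields an empty table).
#' @param geometry geometry parameters, see [discGeometry()].
#' @param modality `"cell"` or `"nucleus"`; sets barcode prefix and the
#'   modality field of the truth table.
#' @param seed integer seed; the same seed reproduces the same table.
#' @return a [S4Vectors::DataFrame] with columns `cell_id`, `radius`,
#'   `angle`, `layer`, `subtype`, `modality`, `degGroup`.
#' @examples
#' truth <- sampleDiscCells(500, seed = 1)
#' table(truth$layer)
#' @export
sampleDiscCells <- function(nCells, geometry = discGeometry(),
                            modality = c("cell", "nucleus"), seed = 1L) {
  modality <- match.arg(modality)
  if (length(nCells) != 1L || is.na(nCells) || nCells < 0)
    stop("nCells must be a single non-negative integer")
  nCells <- as.integer(nCells)
  prefix <- if (modality == "cell") "C" else "N"
  if (nCells == 0L) {
    return(S4Vectors::DataFrame(
      cell_id = character(), radius = numeric(), angle = numeric(),
      layer = character(), subtype = character(), modality = character(),
      degGroup = numeric()))
  }
  set.seed(seed)
  radius <- sqrt(runif(nCells))
  angle <- runif(nCells, 0, 2 * pi)
  layer <- ifelse(radius < geometry$centerCutoff, "endoderm",
                  ifelse(radius > geometry$rimCutoff, "mesoderm",
                         "ectoderm"))
  subtype <- rep("none", nCells)

  drawSubtype <- function(subtype, label, frac, eligible) {
    n <- round(frac * nCells)
    pool <- which(eligible & subtype == "none")
    if (n > 0 && length(pool) > 0) {
      pick <- if (length(pool) <= n) pool else sample(pool, n)
      subtype[pick] <- label
    }
    subtype
  }
  central <- layer == "endoderm" & radius < geometry$centralPocket
  subtype <- drawSubtype(subtype, "CM", geometry$fracCM, central)
  subtype <- drawSubtype(subtype, "cumulus", geometry$fracCumulus, central)
  subtype <- drawSubtype(subtype, "emerging_posterior",
                         geometry$fracEmerging, layer == "endoderm")
  subtype <- drawSubtype(subtype, "caudal_mesoderm", geometry$fracCaudal,
                         layer == "mesoderm")
  rimZone <- layer == "mesoderm" & radius >= geometry$rimCutoff &
    radius <= geometry$rimCutoff + geometry$rimBand
  subtype <- drawSubtype(subtype, "rim_intermediate",
                         geometry$fracRimIntermediate, rimZone)

  # symmetric +/- 0.5 coding keeps the expected library size of the two
  # halves equal, so the artifact shifts relative levels, not depth
  degGroup <- rep(0, nCells)
  ecto <- layer == "ectoderm"
  degGroup[ecto] <- sample(c(-0.5, 0.5), sum(ecto), replace = TRUE)

  S4Vectors::DataFrame(
    cell_id = sprintf("%s%05d", prefix, seq_len(nCells)),
    radius = radius, angle = angle, layer = layer, subtype = subtype,
    modality = modality, degGroup = degGroup)
}

.klassLevels <- c("peripheral", "intermediate", "central", "ubiquitous_deg",
                  "layer_marker", "rare_marker", "emerging", "noise")

#' Construct a gene expression program
#'
#' A gene program describes one gene's expected expression as a function of
#' a cell's radial position, germ layer, subtype and artifact group. The
#' radial response classes mirror concentric Hedgehog-target domains with
#' fuzzy logistic boundaries: `peripheral` genes rise towards the rim,
#' `central` genes towards the centre, `intermediate` genes occupy an
#' annular band. `ubiquitous_deg` genes are expressed everywhere at high
#' level with a log-scale offset between two arbitrary ectodermal halves
#' (the clustering artifact). `layer_marker` and `rare_marker` genes are on
#' in their target layer/subtype only, `emerging` genes mark a nascent
#' central cell state and are boosted in nucleus profiles, and `noise`
#' genes are position-independent background.
#'
#' @param geneId gene identifier.
#' @param klass response class, one of
#'   `r paste0('"', .klassLevels, '"', collapse = ", ")`.
#' @param amplitude expected molecule count at full activation (> 0).
#' @param center domain midpoint in radius units, in [0, 1].
#' @param steepness inverse boundary fuzziness (> 0); larger values give
#'   sharper domain boundaries.
#' @param dispersion negative-binomial size parameter (> 0); `Inf` gives
#'   Poisson counts.
#' @param target layer or subtype the program marks (for `layer_marker`,
#'   `rare_marker` and optionally `emerging`).
#' @param nascentBoost nucleus-modality mean multiplier (>= 1; must be 1
#'   for every class except `emerging`).
#' @param degGroupEffect log-scale offset between artifact groups
#'   (`ubiquitous_deg` only).
#' @param band annulus width in radius units (`intermediate` only).
#' @param leak off-target expression as a fraction of `amplitude`.
#' @return a one-row [S4Vectors::DataFrame]; rows can be concatenated with
#'   `rbind` to build a panel.
#' @export
geneProgram <- function(geneId, klass, amplitude, center = 0.5,
                        steepness = 10, dispersion = 4, target = NA_character_,
                        nascentBoost = 1, degGroupEffect = 0, band = 0.3,
                        leak = 0) {
  klass <- match.arg(klass, .klassLevels)
  if (!is.finite(steepness)) stop("steepness must be finite")
  if (amplitude <= 0) stop("amplitude must be strictly positive")
  if (dispersion <= 0) stop("dispersion must be strictly positive")
  if (klass != "emerging" && nascentBoost != 1)
    stop("nascentBoost must be 1 for klass '", klass, "'")
  if (nascentBoost < 1) stop("nascentBoost must be >= 1")
  S4Vectors::DataFrame(
    gene_id = geneId, klass = klass, amplitude = amplitude, center = center,
    steepness = steepness, dispersion = dispersion, target = target,
    nascentBoost = nascentBoost, degGroupEffect = degGroupEffect,
    band = band, leak = leak)
}

#' Default germ-disc gene panel
#'
#' Builds the standard simulation panel: 48 radially patterned polarity
#' genes (16 each peripheral / intermediate / central, echoing a typical
#' Hedgehog-target panel), a large block of highly expressed ubiquitous
#' genes carrying the ectodermal clustering artifact, per-layer marker
#' genes, a handful of CM-cell and cumulus markers, a few nucleus-sensitive
#' emerging genes, and a sea of low-level noise genes. All block sizes and
#' effect sizes are configurable; the construction is deterministic.
#'
#' @param nPolarityEach polarity genes per class (peripheral, intermediate,
#'   central).
#' @param nUbiquitous number of ubiquitous artifact genes.
#' @param nLayerMarkers markers per germ layer.
#' @param nCMMarkers number of CM-cell rare markers.
#' @param nCumulusMarkers number of cumulus markers.
#' @param nEmerging number of nucleus-sensitive emerging genes.
#' @param nNoise number of background noise genes.
#' @param polarityAmplitude expected molecules at full activation for
#'   polarity genes.
#' @param steepness logistic boundary steepness for polarity genes (radial
#'   fuzziness knob; smaller = fuzzier, more overlapping domains).
#' @param degGroupEffect base magnitude of the log-scale expression offset
#'   between the two artifact halves of the ectoderm; each ubiquitous gene
#'   receives a signed per-gene offset spanning 0.6-1.4 times this value,
#'   balanced in sign across the panel so that the artifact changes
#'   relative expression rather than library depth (0 disables the
#'   artifact).
#' @param ubiquitousAmplitude base expected molecules for ubiquitous genes
#'   (they span a log-spaced range around this value, keeping them far
#'   above the typical gene as in real data where such genes carry an
#'   order of magnitude more molecules).
#' @param markerAmplitude expected molecules for layer markers.
#' @param rareAmplitude expected molecules for CM/cumulus markers.
#' @param emergingAmplitude expected molecules for emerging genes in the
#'   cell modality (before the nucleus-side nascent boost).
#' @param nascentBoost nucleus-modality multiplier for emerging genes.
#' @return a [S4Vectors::DataFrame] of gene programs, one row per gene.
#' @examples
#' panel <- defaultPanel()
#' table(panel$klass)
#' @export
defaultPanel <- function(nPolarityEach = 16, nUbiquitous = 400,
                         nLayerMarkers = 30, nCMMarkers = 9,
                         nCumulusMarkers = 6, nEmerging = 4, nNoise = 1500,
                         polarityAmplitude = 8, steepness = 10,
                         degGroupEffect = 0.9, ubiquitousAmplitude = 6,
                         markerAmplitude = 5, rareAmplitude = 16,
                         emergingAmplitude = 0.6, nascentBoost = 6) {
  rows <- list()
  # vectorised block constructor (building the panel row-by-row through
  # geneProgram() would validate one row at a time and is far slower)
  addRows <- function(ids, klass, amplitude, center = 0.5, steepness = 10,
                      dispersion = 4, target = NA_character_,
                      nascentBoost = 1, degGroupEffect = 0, band = 0.3,
                      leak = 0) {
    rows[[length(rows) + 1L]] <<- S4Vectors::DataFrame(
      gene_id = ids, klass = klass, amplitude = amplitude, center = center,
      steepness = steepness, dispersion = dispersion, target = target,
      nascentBoost = nascentBoost, degGroupEffect = degGroupEffect,
      band = band, leak = leak)
  }
  idfmt <- function(pfx, n) sprintf("%s%04d", pfx, seq_len(n))

  if (nPolarityEach > 0) {
    addRows(idfmt("PER", nPolarityEach), klass = "peripheral",
            amplitude = polarityAmplitude,
            center = seq(0.55, 0.90, length.out = nPolarityEach),
            steepness = steepness)
    addRows(idfmt("INT", nPolarityEach), klass = "intermediate",
            amplitude = polarityAmplitude,
            center = seq(0.30, 0.70, length.out = nPolarityEach),
            steepness = steepness + 2, band = 0.3)
    addRows(idfmt("CEN", nPolarityEach), klass = "central",
            amplitude = polarityAmplitude,
            center = seq(0.10, 0.45, length.out = nPolarityEach),
            steepness = steepness)
  }
  if (nUbiquitous > 0)
    addRows(idfmt("UBQ", nUbiquitous), klass = "ubiquitous_deg",
            amplitude = exp(seq(log(ubiquitousAmplitude / 1.5),
                                log(ubiquitousAmplitude * 1.5),
                                length.out = nUbiquitous)),
            dispersion = 8,
            # signed per-gene offsets, balanced across the panel so the
            # artifact shifts relative levels rather than library depth
            degGroupEffect = rep_len(c(1, -1), nUbiquitous) *
              degGroupEffect * seq(0.6, 1.4, length.out = nUbiquitous))
  if (nLayerMarkers > 0) {
    for (ly in c("ectoderm", "mesoderm", "endoderm")) {
      pfx <- paste0("MK", toupper(substr(ly, 1, 3)))
      addRows(idfmt(pfx, nLayerMarkers), klass = "layer_marker",
              amplitude = markerAmplitude, target = ly)
    }
  }
  if (nCMMarkers > 0)
    addRows(idfmt("CMM", nCMMarkers), klass = "rare_marker",
            amplitude = rareAmplitude, dispersion = 12, target = "CM")
  if (nCumulusMarkers > 0)
    addRows(idfmt("CUM", nCumulusMarkers), klass = "rare_marker",
            amplitude = rareAmplitude * 1.25, dispersion = 6,
            target = "cumulus")
  if (nEmerging > 0)
    addRows(idfmt("EMG", nEmerging), klass = "emerging",
            amplitude = emergingAmplitude, center = 0.45,
            nascentBoost = nascentBoost, target = "emerging_posterior")
  if (nNoise > 0)
    addRows(idfmt("NSE", nNoise), klass = "noise",
            amplitude = seq(0.05, 0.5, length.out = nNoise), dispersion = 1)

  panel <- do.call(rbind, rows)
  rownames(panel) <- panel$gene_id
  panel
}

#' Gene ids of the radial polarity panel
#'
#' @param panel a gene-program table as built by [defaultPanel()].
#' @return character vector of peripheral/intermediate/central gene ids.
#' @export
polarityPanelGenes <- function(panel) {
  panel$gene_id[panel$klass %in% c("peripheral", "intermediate", "central")]
}

#' Expected expression of a gene program across cells
#'
#' Evaluates the noiseless expected molecule count of one gene program for
#' each cell of a truth table. Radial classes use logistic responses:
#' peripheral `A * s(k (r - c))`, central `A * s(k (c - r))`, and
#' intermediate `A * s(k (r - cLo)) * s(k (cHi - r))` with
#' `cLo = c - band/2`, `cHi = c + band/2`, where `s` is the logistic
#' function, `A` the amplitude, `k` the steepness and `r` the cell radius.
#' Marker classes return `A` on target and `leak * A` off target
#' (rim-intermediate cells receive half-amplitude expression of both
#' ectodermal and mesodermal layer markers). Emerging genes follow a
#' central envelope, restricted to their target subtype when one is set,
#' and are multiplied by `nascentBoost` in the nucleus modality.
#'
#' @param program a one-row gene-program table ([geneProgram()]).
#' @param truth a cell truth table ([sampleDiscCells()]).
#' @param modality `"cell"` or `"nucleus"`; defaults to the truth table's
#'   own modality.
#' @return numeric vector of expected counts, one per cell.
#' @export
spatialMean <- function(program, truth, modality = NULL) {
  stopifnot(nrow(program) == 1L)
  if (is.null(modality)) {
    modality <- if (nrow(truth) > 0) truth$modality[1] else "cell"
  }
  modality <- match.arg(modality, c("cell", "nucleus"))
  A <- program$amplitude
  k <- program$steepness
  cc <- program$center
  r <- truth$radius
  leak <- program$leak
  mu <- switch(program$klass,
    peripheral = A * .sigmoid(k * (r - cc)),
    central = A * .sigmoid(k * (cc - r)),
    intermediate = {
      cLo <- cc - program$band / 2
      cHi <- cc + program$band / 2
      A * .sigmoid(k * (r - cLo)) * .sigmoid(k * (cHi - r))
    },
    ubiquitous_deg = A * exp(program$degGroupEffect * truth$degGroup),
    layer_marker = {
      on <- truth$layer == program$target
      half <- truth$subtype == "rim_intermediate" &
        program$target %in% c("ectoderm", "mesoderm")
      A * ifelse(on & !half, 1, ifelse(half, 0.5, leak))
    },
    rare_marker = A * ifelse(truth$subtype == program$target, 1, leak),
    emerging = {
      env <- .sigmoid(k * (cc - r))
      gate <- if (is.na(program$target)) rep(1, nrow(truth)) else
        ifelse(truth$subtype == program$target, 1, leak)
      boost <- if (modality == "nucleus") program$nascentBoost else 1
      A * env * gate * boost
    },
    noise = rep(A, nrow(truth)),
    stop("unknown klass: ", program$klass))
  as.numeric(mu)
}

#' Per-modality sequencing depth parameters
#'
#' Cell size factors are lognormal with unit mean times the modality depth
#' scale; the nucleus modality captures a configurable fraction (default
#' one third) of the cell modality's molecules, matching the depth contrast
#' between whole-cell and nucleus-only libraries.
#'
#' @param cellScale mean depth scale of the cell modality (multiplies every
#'   gene's expected count).
#' @param nucleusFraction nucleus depth as a fraction of the cell depth.
#' @param sigma lognormal standard deviation of per-cell size factors.
#' @return named list of depth parameters.
#' @export
depthParams <- function(cellScale = 1, nucleusFraction = 1 / 3,
                        sigma = 0.25) {
  stopifnot(cellScale > 0, nucleusFraction > 0, sigma >= 0)
  list(cellScale = cellScale, nucleusFraction = nucleusFraction,
       sigma = sigma)
}

#' Simulate a germ-disc count matrix from truth and a gene panel
#'
#' Counts are negative binomial: `count(g, c) ~ NB(mean = mu(g, c) * sf(c),
#' size = dispersion(g))` where `mu` is [spatialMean()] and `sf` a
#' lognormal per-cell size factor (unit mean, times the modality depth
#' scale). Setting `poisson = TRUE` (or a program dispersion of `Inf`)
#' replaces the NB draw by its Poisson limit, which is convenient for
#' closed-form checks. Optionally appends low-complexity cells (few genes
#' detected) and doublets (the summed counts of two random cells) for
#' exercising quality-control filters; these extra columns are flagged in
#' the `qcClass` column of the cell metadata.
#'
#' @param truth cell truth table from [sampleDiscCells()].
#' @param panel gene-program table from [defaultPanel()] or built by hand.
#' @param depth depth parameters, see [depthParams()].
#' @param seed integer seed; the same seed reproduces the matrix exactly.
#' @param poisson logical; force Poisson sampling for all genes.
#' @param nLowComplexity number of spiked low-complexity cells.
#' @param lowComplexityGenes genes detected per low-complexity cell.
#' @param nDoublets number of spiked doublet cells.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   `counts` assay, the truth table (plus `qcClass`) as column data, the
#'   panel as row data and a provenance list in the metadata.
#' @examples
#' truth <- sampleDiscCells(100, seed = 1)
#' sce <- simulateCounts(truth, defaultPanel(nUbiquitous = 20, nNoise = 50),
#'                       seed = 1)
#' dim(sce)
#' @export
simulateCounts <- function(truth, panel, depth = depthParams(), seed = 1L,
                           poisson = FALSE, nLowComplexity = 0L,
                           lowComplexityGenes = 50L, nDoublets = 0L) {
  if (nrow(panel) == 0L) stop("panel must contain at least one gene program")
  if (anyDuplicated(panel$gene_id)) stop("duplicate gene ids in panel")
  nCells <- nrow(truth)
  modality <- if (nCells > 0) truth$modality[1] else "cell"
  set.seed(seed)
  scale <- depth$cellScale *
    if (modality == "nucleus") depth$nucleusFraction else 1
  sf <- scale * rlnorm(nCells, meanlog = -depth$sigma^2 / 2,
                       sdlog = depth$sigma)

  counts <- matrix(0L, nrow = nrow(panel), ncol = nCells,
                   dimnames = list(panel$gene_id, truth$cell_id))
  panelDF <- as.data.frame(panel)   # plain rows: fast per-gene access
  truthDF <- as.data.frame(truth)
  if (nCells > 0) {
    for (g in seq_len(nrow(panel))) {
      mu <- spatialMean(panelDF[g, , drop = FALSE], truthDF, modality) * sf
      size <- panel$dispersion[g]
      counts[g, ] <- if (poisson || !is.finite(size)) rpois(nCells, mu)
        else rnbinom(nCells, mu = mu, size = size)
    }
  }

  qcClass <- rep("normal", nCells)
  if (nCells > 0 && nLowComplexity > 0) {
    lc <- matrix(0L, nrow(panel), nLowComplexity,
                 dimnames = list(panel$gene_id,
                                 sprintf("LOWCOMP%04d", seq_len(nLowComplexity))))
    for (j in seq_len(nLowComplexity)) {
      g <- sample(nrow(panel), min(lowComplexityGenes, nrow(panel)))
      lc[g, j] <- rpois(length(g), 2) + 1L
    }
    counts <- cbind(counts, lc)
    qcClass <- c(qcClass, rep("low_complexity", nLowComplexity))
  }
  if (nCells >= 2 && nDoublets > 0) {
    db <- matrix(0L, nrow(panel), nDoublets,
                 dimnames = list(panel$gene_id,
                                 sprintf("DOUBLET%04d", seq_len(nDoublets))))
    for (j in seq_len(nDoublets)) {
      pair <- sample(nCells, 2)
      db[, j] <- counts[, pair[1]] + counts[, pair[2]]
    }
    counts <- cbind(counts, db)
    qcClass <- c(qcClass, rep("doublet", nDoublets))
  }

  nExtra <- length(qcClass) - nCells
  cd <- if (nExtra > 0) {
    extra <- S4Vectors::DataFrame(
      cell_id = colnames(counts)[nCells + seq_len(nExtra)],
      radius = NA_real_, angle = NA_real_, layer = NA_character_,
      subtype = NA_character_, modality = modality, degGroup = NA_real_)
    rbind(truth, extra)
  } else truth
  cd$qcClass <- qcClass
  rownames(cd) <- cd$cell_id

  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = as(counts, "CsparseMatrix")),
    colData = cd, rowData = panel,
    metadata = list(provenance = list(
      generator = "scPolarity::simulateCounts", seed = seed,
      modality = modality, depth = depth, poisson = poisson,
      nLowComplexity = nLowComplexity, nDoublets = nDoublets)))
}

#' One-call germ-disc simulation
#'
#' Convenience wrapper: samples a truth table with [sampleDiscCells()] and
#' simulates counts with [simulateCounts()], deriving distinct stage seeds
#' from the single seed argument.
#'
#' @inheritParams sampleDiscCells
#' @inheritParams simulateCounts
#' @param ... passed on to [simulateCounts()].
#' @return a [SingleCellExperiment::SingleCellExperiment], as
#'   [simulateCounts()].
#' @examples
#' sce <- simulateGermDisc(200, panel = defaultPanel(nUbiquitous = 20,
#'                                                   nNoise = 50), seed = 7)
#' sce
#' @export
simulateGermDisc <- function(nCells = 2000, modality = c("cell", "nucleus"),
                             geometry = discGeometry(),
                             panel = defaultPanel(), depth = depthParams(),
                             seed = 1L, ...) {
  modality <- match.arg(modality)
  truth <- sampleDiscCells(nCells, geometry, modality,
                           seed = .stageSeed(seed, "cells"))
  simulateCounts(truth, panel, depth,
                 seed = .stageSeed(seed, paste0("counts_", modality)), ...)
}

#' Cell truth accessor
#'
#' @param sce a simulated [SingleCellExperiment::SingleCellExperiment].
#' @return the cell truth table stored in the column data.
#' @export
cellTruth <- function(sce) SummarizedExperiment::colData(sce)

#' Gene panel accessor
#'
#' @param sce a simulated [SingleCellExperiment::SingleCellExperiment].
#' @return the gene-program table stored in the row data.
#' @export
genePanel <- function(sce) SummarizedExperiment::rowData(sce)
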