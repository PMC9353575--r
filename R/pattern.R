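# Shared rasterisation core: maps embedding coordinates onto a pixel grid
# with a margin, splats each cell as a small disc, and aggregates
# overlapping splats. Returns the (cellSplat index -> pixel index) mapping
# so that many genes can be rendered against one geometry cheaply.
.rasterGeometry <- function(emb, width, height, splatRadius, margin) {
  if (any(!is.finite(emb))) stop("embedding coordinates must be finite")
  if (width < 8 || height < 8) stop("raster must be at least 8x8 pixels")
  xr <- range(emb[, 1]); yr <- range(emb[, 2])
  pad <- function(r) {
    w <- diff(r); if (w == 0) w <- 1
    r + c(-1, 1) * margin * w
  }
  xr <- pad(xr); yr <- pad(yr)
  col <- pmin(width - 1L, pmax(0L, floor((emb[, 1] - xr[1]) /
                                           diff(xr) * width)))
  row <- pmin(height - 1L, pmax(0L, floor((emb[, 2] - yr[1]) /
                                            diff(yr) * height)))
  off <- expand.grid(dx = -splatRadius:splatRadius,
                     dy = -splatRadius:splatRadius)
  off <- off[off$dx^2 + off$dy^2 <= splatRadius^2, , drop = FALSE]
  cellIdx <- rep(seq_len(nrow(emb)), each = nrow(off))
  px <- rep(col, each = nrow(off)) + off$dx
  py <- rep(row, each = nrow(off)) + off$dy
  ok <- px >= 0 & px < width & py >= 0 & py < height
  list(cellIdx = cellIdx[ok], pixIdx = py[ok] + 1L + height * px[ok],
       extent = c(xmin = xr[1], xmax = xr[2], ymin = yr[1], ymax = yr[2]))
}

.renderGene <- function(values, geom, nPix, aggregation) {
  img <- numeric(nPix)
  v <- values[geom$cellIdx]
  if (aggregation == "max") {
    ord <- order(v, decreasing = TRUE)
    first <- !duplicated(geom$pixIdx[ord])
    img[geom$pixIdx[ord][first]] <- v[ord][first]
  } else {
    sums <- rowsum(v, geom$pixIdx)
    cnts <- rowsum(rep(1, length(v)), geom$pixIdx)
    img[as.integer(rownames(sums))] <- sums / cnts
  }
  img
}

#' Rasterise a whole gene panel onto one embedding
#'
#' Renders every requested gene's normalised expression as a grayscale
#' image on the shared 2D embedding. The embedding extent is mapped
#' linearly onto the pixel grid with a 5% margin; each cell splats a disc
#' of `splatRadius` pixels; overlapping splats are combined by the
#' aggregation rule. Intensities are divided by a single panel-wide
#' normalisation constant (the 99th percentile of all rendered values,
#' or per-gene maxima with `normalizeBy = "gene"`) and clipped to 1, so
#' that ubiquitous dim genes do not mimic patterned ones. Pixels covered
#' by no cell are exactly 0, the zero-expression background.
#'
#' @param emb cells x 2 embedding ([embed2D()]).
#' @param x object carrying a `lognorm` assay, or a normalised matrix,
#'   whose columns cover the embedding cells.
#' @param genes gene ids to render (default: all genes).
#' @param width,height raster size in pixels.
#' @param splatRadius disc radius in pixels splatted per cell.
#' @param aggregation `"max"` or `"mean"` for overlapping splats.
#' @param margin fractional margin added around the embedding extent.
#' @param normalizeBy `"panel"` (shared 99th-percentile constant) or
#'   `"gene"` (each gene scaled by its own maximum).
#' @param normQuantile quantile defining the panel-wide constant.
#' @return an [ExpressionImageSet].
#' @export
rasterizePanel <- function(emb, x, genes = NULL, width = 256, height = 256,
                           splatRadius = 2, aggregation = c("max", "mean"),
                           margin = 0.05, normalizeBy = c("panel", "gene"),
                           normQuantile = 0.99) {
  aggregation <- match.arg(aggregation)
  normalizeBy <- match.arg(normalizeBy)
  norm <- .getLogNorm(x)
  if (is.null(genes)) genes <- rownames(norm)
  missing <- setdiff(c(genes, character()), rownames(norm))
  if (length(missing) > 0) stop("unknown genes: ", missing[1])
  if (!all(rownames(emb) %in% colnames(norm)))
    stop("normalised values must cover every embedded cell")
  vals <- as.matrix(norm[genes, rownames(emb), drop = FALSE])
  geom <- .rasterGeometry(emb, width, height, splatRadius, margin)
  nPix <- width * height
  scaleMax <- if (normalizeBy == "panel") {
    q <- quantile(vals[vals > 0], normQuantile, names = FALSE)
    if (!is.finite(q) || q <= 0) 1 else q
  } else NA_real_
  ints <- matrix(0, nPix, length(genes),
                 dimnames = list(NULL, genes))
  for (j in seq_along(genes)) {
    img <- .renderGene(vals[j, ], geom, nPix, aggregation)
    s <- if (normalizeBy == "panel") scaleMax else max(img, 1e-12)
    ints[, j] <- pmin(img / s, 1)
  }
  new("ExpressionImageSet", intensities = ints, width = as.integer(width),
      height = as.integer(height), geneIds = genes,
      provenance = list(extent = geom$extent, width = as.integer(width),
                        height = as.integer(height),
                        splatRadius = splatRadius,
                        aggregation = aggregation, margin = margin,
                        normalizeBy = normalizeBy,
                        scaleMax = if (normalizeBy == "panel") scaleMax
                                   else NA_real_))
}

#' Rasterise one gene's expression
#'
#' Single-gene convenience wrapper around the panel rasteriser; by default
#' the gene is normalised by its own maximum (`scaleMax = NULL`), or by a
#' supplied constant for comparability across genes.
#'
#' @inheritParams rasterizePanel
#' @param values named per-cell expression values covering the embedding.
#' @param geneId identifier stored in the image.
#' @param scaleMax normalisation constant; `NULL` uses the value maximum.
#' @return an [ExpressionImage].
#' @export
rasterizeExpression <- function(emb, values, geneId = "gene", width = 256,
                                height = 256, splatRadius = 2,
                                aggregation = c("max", "mean"),
                                margin = 0.05, scaleMax = NULL) {
  aggregation <- match.arg(aggregation)
  if (!all(rownames(emb) %in% names(values)))
    stop("values must cover every embedded cell")
  geom <- .rasterGeometry(emb, width, height, splatRadius, margin)
  img <- .renderGene(values[rownames(emb)], geom, width * height,
                     aggregation)
  s <- if (is.null(scaleMax)) max(img, 1e-12) else scaleMax
  new("ExpressionImage",
      intensities = matrix(pmin(img / s, 1), height, width),
      geneId = geneId,
      provenance = list(extent = geom$extent, width = as.integer(width),
                        height = as.integer(height),
                        splatRadius = splatRadius,
                        aggregation = aggregation, margin = margin,
                        scaleMax = s))
}

#' Normalised cross-correlation between two equal-size patches
#'
#' The Pearson-style matching score used in template matching
#' (the "normalized correlation coefficient" method):
#' `R = sum((T - mean(T)) * (P - mean(P))) /
#'  sqrt(sum((T - mean(T))^2) * sum((P - mean(P))^2))`.
#' By convention the score is 0 when either patch has zero variance (the
#' comparison is then uninformative); this situation is reported via a
#' message.
#'
#' @param template,patch numeric matrices of identical dimensions with at
#'   least 4 pixels.
#' @return a single number in [-1, 1].
#' @examples
#' a <- matrix(runif(35), 7, 5)
#' ncc(a, 2 * a + 1)   # affine invariance: exactly 1
#' @export
ncc <- function(template, patch) {
  if (!all(dim(template) == dim(patch)))
    stop("template and patch must have identical dimensions")
  if (length(template) < 4) stop("patches must contain at least 4 pixels")
  t0 <- template - mean(template)
  p0 <- patch - mean(patch)
  denom <- sqrt(sum(t0^2) * sum(p0^2))
  if (denom == 0) {
    message("zero-variance patch in ncc(); returning 0 by convention")
    return(0)
  }
  sum(t0 * p0) / denom
}

#' Rectangular template query on expression images
#'
#' @param geneId gene whose image supplies the template.
#' @param x0,y0 top-left pixel of the rectangle (0-based; `x0` is the
#'   column, `y0` the row).
#' @param w,h rectangle width and height in pixels (each at least 2).
#' @param mode `"fixed"` compares the same rectangle across genes;
#'   `"slide"` scans the template over each gene's full image.
#' @return a `TemplateQuery` list.
#' @export
templateQuery <- function(geneId, x0, y0, w, h,
                          mode = c("fixed", "slide")) {
  mode <- match.arg(mode)
  if (w < 2 || h < 2) stop("template must be at least 2x2 pixels")
  if (x0 < 0 || y0 < 0) stop("rectangle origin must be non-negative")
  structure(list(geneId = geneId, x0 = as.integer(x0), y0 = as.integer(y0),
                 w = as.integer(w), h = as.integer(h), mode = mode),
            class = "TemplateQuery")
}

# linear pixel indices (column-major, height rows) of a rectangle
.rectIndices <- function(x0, y0, w, h, height) {
  as.vector(outer(y0 + seq_len(h), height * (x0 + seq_len(w) - 1L), "+"))
}

#' Search all genes' expression images for a template pattern
#'
#' Crops the query rectangle from the query gene's image and scores every
#' gene in the image set against it with the normalised correlation
#' coefficient ([ncc()]). In `fixed` mode the same rectangle of each
#' gene's image is scored (the corresponding area of each plot); in
#' `slide` mode the template is scanned over every in-bounds offset of
#' each image and the best score and its offset are reported. Genes whose
#' patch has zero variance score 0 by convention. Hits are sorted by
#' score (descending, ties broken by gene id); the query gene itself is
#' included and scores 1 in fixed mode.
#'
#' @param query a [templateQuery()].
#' @param images an [ExpressionImageSet] sharing one raster provenance.
#' @return data.frame with columns `gene_id`, `score`, `x0`, `y0`
#'   (match location: the query rectangle in fixed mode, the best offset
#'   in slide mode).
#' @export
templateSearch <- function(query, images) {
  stopifnot(inherits(query, "TemplateQuery"), is(images, "ExpressionImageSet"))
  W <- images@width; H <- images@height
  if (query$x0 + query$w > W || query$y0 + query$h > H)
    stop("query rectangle exceeds image bounds")
  j <- match(query$geneId, images@geneIds)
  if (is.na(j)) stop("query gene '", query$geneId, "' not in image set")
  rect <- .rectIndices(query$x0, query$y0, query$w, query$h, H)
  tmpl <- images@intensities[rect, j]
  t0 <- tmpl - mean(tmpl)
  tss <- sum(t0^2)
  if (tss == 0)
    warning("template has zero variance; all scores are 0 by convention")

  if (query$mode == "fixed") {
    patches <- images@intensities[rect, , drop = FALSE]
    p0 <- sweep(patches, 2, colMeans(patches))
    pss <- colSums(p0^2)
    denom <- sqrt(tss * pss)
    scores <- ifelse(denom > 0, colSums(p0 * tmpl) / denom, 0)
    out <- data.frame(gene_id = images@geneIds, score = as.numeric(scores),
                      x0 = query$x0, y0 = query$y0,
                      stringsAsFactors = FALSE)
  } else {
    tm <- matrix(t0, query$h, query$w)
    out <- do.call(rbind, lapply(seq_along(images@geneIds), function(g) {
      img <- matrix(images@intensities[, g], H, W)
      best <- .slideNCC(img, tm, tss)
      data.frame(gene_id = images@geneIds[g], score = best$score,
                 x0 = best$x0, y0 = best$y0, stringsAsFactors = FALSE)
    }))
  }
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Sliding NCC via FFT cross-correlation for the numerator and integral
# images for the local patch variance. tm is the mean-centred template.
.slideNCC <- function(img, tm, tss) {
  H <- nrow(img); W <- ncol(img)
  h <- nrow(tm); w <- ncol(tm)
  if (tss == 0) return(list(score = 0, x0 = 0L, y0 = 0L))
  pad <- matrix(0, H, W)
  pad[seq_len(h), seq_len(w)] <- tm
  num <- Re(stats::fft(stats::fft(img) * Conj(stats::fft(pad)),
                       inverse = TRUE)) / (H * W)
  ii1 <- apply(apply(rbind(0, cbind(0, img)), 2, cumsum), 1, cumsum)
  ii2 <- apply(apply(rbind(0, cbind(0, img^2)), 2, cumsum), 1, cumsum)
  # ii is (W+1) x (H+1) after the double transpose-cumsum; index as [x, y]
  rectSum <- function(ii, y0, x0) {
    ii[x0 + w + 1, y0 + h + 1] - ii[x0 + 1, y0 + h + 1] -
      ii[x0 + w + 1, y0 + 1] + ii[x0 + 1, y0 + 1]
  }
  oy <- 0:(H - h); ox <- 0:(W - w)
  best <- list(score = -Inf, x0 = 0L, y0 = 0L)
  n <- h * w
  for (x in ox) {
    s1 <- vapply(oy, function(y) rectSum(ii1, y, x), numeric(1))
    s2 <- vapply(oy, function(y) rectSum(ii2, y, x), numeric(1))
    pvar <- s2 - s1^2 / n
    nm <- num[oy + 1, x + 1]
    sc <- numeric(length(pvar))
    ok <- pvar > 1e-12
    sc[ok] <- nm[ok] / sqrt(tss * pvar[ok])
    i <- which.max(sc)
    if (sc[i] > best$score)
      best <- list(score = sc[i], x0 = as.integer(x),
                   y0 = as.integer(oy[i]))
  }
  best
}

#' RGB composite of two or three expression images
#'
#' Each image is transformed into its negative (1 - intensity) and
#' assigned to a colour channel, so non-expressing regions are white and
#' each gene's domain appears in its channel's colour; overlap appears in
#' mixed colours. A missing third channel is filled with the all-ones
#' white-background plane.
#'
#' @param images list of 2 or 3 [ExpressionImage] objects of equal size.
#' @param channels order in which images are assigned to R, G, B.
#' @return height x width x 3 numeric array with values in [0, 1].
#' @export
compositeRGB <- function(images, channels = seq_along(images)) {
  if (length(images) < 2 || length(images) > 3)
    stop("need 2 or 3 images")
  mats <- lapply(images, intensities)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == d), logical(1))))
    stop("images must share dimensions")
  mats <- mats[order(channels)]
  out <- array(1, c(d, 3))
  for (ch in seq_along(mats)) out[, , ch] <- 1 - mats[[ch]]
  out
}

#' Rare-cell marker filter
#'
#' Finds genes that mark a single rare cell (such as a cumulus mesenchymal
#' cell): genes whose normalised value in the target cell exceeds
#' `exprThreshold` and whose expression is detected (value > 0) in
#' strictly fewer than `maxDetectedCells` cells overall. Results are
#' ranked by the value in the target cell (descending), ties broken by
#' fewer detected cells and then by gene id.
#'
#' @param x object carrying a `lognorm` assay, or a normalised matrix.
#' @param targetCell barcode of the cell of interest.
#' @param exprThreshold minimum normalised value in the target cell
#'   (strict).
#' @param maxDetectedCells strict upper bound on the number of cells in
#'   which a retained gene is detected.
#' @return data.frame with columns `gene_id`, `value_in_target`,
#'   `n_cells_detected`.
#' @export
rareCellMarkers <- function(x, targetCell, exprThreshold = 2,
                            maxDetectedCells = 20L) {
  norm <- .getLogNorm(x)
  j <- match(targetCell, colnames(norm))
  if (is.na(j)) stop("unknown barcode: ", targetCell)
  v <- as.numeric(norm[, j])
  nDet <- as.integer(Matrix::rowSums(norm > 0))
  keep <- which(v > exprThreshold & nDet < maxDetectedCells)
  out <- data.frame(gene_id = rownames(norm)[keep],
                    value_in_target = v[keep],
                    n_cells_detected = nDet[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$value_in_target, out$n_cells_detected,
                   out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
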