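#' @import methods
#' @importFrom stats cor dist hclust median p.adjust pnorm quantile
#'   rlnorm rnbinom rnorm rpois runif sd setNames var
#' @importFrom utils head
NULL

#' ExpressionImage: a gene's expression rendered on a 2D embedding
#'
#' A fixed-size grayscale raster of one gene's (normalised) expression on a
#' 2D embedding. Pixels covered by no cell carry exactly the zero-expression
#' intensity 0, so that the image background equals the colour of
#' non-expressing cells; this is what makes template matching on these
#' images meaningful.
#'
#' @slot intensities numeric matrix (height x width), values in [0, 1].
#' @slot geneId single character gene identifier.
#' @slot provenance named list describing how the raster was produced:
#'   embedding extent, raster size, splat radius, aggregation rule and the
#'   normalisation constant. Images are only comparable (e.g. in
#'   [templateSearch()]) when their provenance agrees.
#'
#' @seealso [rasterizeExpression()], [rasterizePanel()], [templateSearch()]
#' @export
setClass("ExpressionImage",
  representation(
    intensities = "matrix",
    geneId = "character",
    provenance = "list"
  )
)

setValidity("ExpressionImage", function(object) {
  ints <- object@intensities
  if (!is.numeric(ints)) return("intensities must be numeric")
  if (any(!is.finite(ints))) return("intensities must be finite")
  if (any(ints < 0) || any(ints > 1 + 1e-12))
    return("intensities must lie in [0, 1]")
  if (length(object@geneId) != 1L) return("geneId must be length 1")
  TRUE
})

#' ExpressionImageSet: rasters for a panel of genes on a shared embedding
#'
#' Holds one [ExpressionImage]-style raster per gene, all produced with the
#' same embedding, extent and raster parameters so they can be compared
#' pixel-by-pixel. Internally the images are stored as a (pixels x genes)
#' matrix for fast whole-panel template matching.
#'
#' @slot intensities numeric matrix with `width * height` rows (pixels in
#'   column-major image order) and one column per gene; values in [0, 1].
#' @slot width,height integer raster size in pixels.
#' @slot geneIds character vector of gene identifiers (column names).
#' @slot provenance shared raster provenance, as for [ExpressionImage].
#'
#' @export
setClass("ExpressionImageSet",
  representation(
    intensities = "matrix",
    width = "integer",
    height = "integer",
    geneIds = "character",
    provenance = "list"
  )
)

setValidity("ExpressionImageSet", function(object) {
  if (nrow(object@intensities) != object@width * object@height)
    return("intensities must have width*height rows")
  if (ncol(object@intensities) != length(object@geneIds))
    return("one column per gene required")
  if (anyDuplicated(object@geneIds)) return("duplicate gene ids")
  TRUE
})

#' PolarityReport: agreement between a reconstructed axis and the true radius
#'
#' Produced by [polarityScore()]. The reconstructed per-cell axis coordinate
#' is compared against the simulated radial position (0 = disc
#' centre/posterior pole, 1 = rim/anterior); because the sign of a principal
#' axis is arbitrary, absolute correlations are reported.
#'
#' @slot axis named numeric vector: per-cell axis coordinate.
#' @slot spearmanAbs absolute Spearman correlation between axis and true
#'   radius over the evaluated subset, in [0, 1].
#' @slot clusterOrderTau absolute Kendall tau between the order of cluster
#'   centroids along the axis and the order of cluster mean true radii
#'   (NA when no cluster assignment was supplied), in [0, 1].
#' @slot subset single character describing the evaluated cell subset.
#'
#' @seealso [polarityAxis()], [polarityScore()]
#' @export
setClass("PolarityReport",
  representation(
    axis = "numeric",
    spearmanAbs = "numeric",
    clusterOrderTau = "numeric",
    subset = "character"
  )
)

setValidity("PolarityReport", function(object) {
  if (length(object@spearmanAbs) != 1L) return("spearmanAbs must be length 1")
  s <- object@spearmanAbs
  if (!is.na(s) && (s < 0 || s > 1)) return("spearmanAbs must be in [0, 1]")
  tau <- object@clusterOrderTau
  if (length(tau) != 1L) return("clusterOrderTau must be length 1")
  if (!is.na(tau) && (tau < 0 || tau > 1))
    return("clusterOrderTau must be in [0, 1]")
  TRUE
})

#' @describeIn ExpressionImage-class raster matrix accessor
#' @param x an `ExpressionImage`, `ExpressionImageSet` or `PolarityReport`.
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @export
setMethod("intensities", "ExpressionImage", function(x) x@intensities)

#' @export
setMethod("intensities", "ExpressionImageSet", function(x) x@intensities)

#' @describeIn ExpressionImage-class gene identifier accessor
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))

#' @export
setMethod("geneId", "ExpressionImage", function(x) x@geneId)

#' @describeIn ExpressionImageSet-class gene identifiers
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @export
setMethod("geneIds", "ExpressionImageSet", function(x) x@geneIds)

#' @describeIn ExpressionImage-class raster provenance accessor
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @export
setMethod("provenance", "ExpressionImage", function(x) x@provenance)

#' @export
setMethod("provenance", "ExpressionImageSet", function(x) x@provenance)

#' Extract one gene's image from an ExpressionImageSet
#'
#' @param x an `ExpressionImageSet`.
#' @param gene gene identifier.
#' @return an [ExpressionImage].
#' @export
getImage <- function(x, gene) {
  stopifnot(is(x, "ExpressionImageSet"))
  j <- match(gene, x@geneIds)
  if (is.na(j)) stop("gene '", gene, "' not in image set")
  new("ExpressionImage",
    intensities = matrix(x@intensities[, j], nrow = x@height,
                         ncol = x@width),
    geneId = gene, provenance = x@provenance)
}

#' @describeIn PolarityReport-class per-cell axis coordinates
#' @export
setGeneric("axisValues", function(x) standardGeneric("axisValues"))

#' @export
setMethod("axisValues", "PolarityReport", function(x) x@axis)

#' @describeIn PolarityReport-class absolute Spearman correlation vs radius
#' @export
setGeneric("spearmanAbs", function(x) standardGeneric("spearmanAbs"))

#' @export
setMethod("spearmanAbs", "PolarityReport", function(x) x@spearmanAbs)

#' @describeIn PolarityReport-class absolute Kendall tau of cluster order
#' @export
setGeneric("clusterOrderTau", function(x) standardGeneric("clusterOrderTau"))

#' @export
setMethod("clusterOrderTau", "PolarityReport", function(x) x@clusterOrderTau)

setMethod("show", "ExpressionImage", function(object) {
  cat("ExpressionImage for gene", object@geneId, "\n")
  cat(" ", nrow(object@intensities), "x", ncol(object@intensities),
      "pixels; intensity range [",
      format(min(object@intensities), digits = 3), ",",
      format(max(object@intensities), digits = 3), "]\n")
})

setMethod("show", "ExpressionImageSet", function(object) {
  cat("ExpressionImageSet:", length(object@geneIds), "genes at",
      object@height, "x", object@width, "pixels\n")
  cat("  splat radius", object@provenance$splatRadius,
      "| aggregation", object@provenance$aggregation,
      "| normalisation", format(object@provenance$scaleMax, digits = 4), "\n")
})

setMethod("show", "PolarityReport", function(object) {
  cat("PolarityReport over", length(object@axis), "cells (",
      object@subset, ")\n")
  cat("  |Spearman(axis, radius)| =",
      format(object@spearmanAbs, digits = 3), "\n")
  if (!is.na(object@clusterOrderTau))
    cat("  |Kendall tau| of cluster order =",
        format(object@clusterOrderTau, digits = 3), "\n")
})
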