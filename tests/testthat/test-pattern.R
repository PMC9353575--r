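test_that("rasterisation pins the background to zero expression", {
  set.seed(30)
  emb <- cbind(runif(40), runif(40))
  rownames(emb) <- sprintf("c%02d", 1:40)
  zeros <- setNames(rep(0, 40), rownames(emb))
  img <- rasterizeExpression(emb, zeros, width = 32, height = 32)
  expect_true(all(intensities(img) == 0))

  one <- matrix(c(0.5, 0.5), 1, dimnames = list("c01", NULL))
  img1 <- rasterizeExpression(one, c(c01 = 3), width = 33, height = 33,
                              splatRadius = 1)
  on <- which(intensities(img1) > 0, arr.ind = TRUE)
  expect_equal(nrow(on), 5)  # centre pixel plus 4-neighbourhood
  ctr <- c(median(on[, 1]), median(on[, 2]))
  expect_true(all(abs(on[, 1] - ctr[1]) + abs(on[, 2] - ctr[2]) <= 1))

  expect_error(rasterizeExpression(matrix(c(NA, 1), 1,
                                          dimnames = list("c01", NULL)),
                                   c(c01 = 1)), "finite")
})

test_that("doubling the raster preserves each cell's quadrant", {
  set.seed(31)
  emb <- cbind(rnorm(60), rnorm(60))
  rownames(emb) <- sprintf("c%02d", 1:60)
  v <- setNames(runif(60, 1, 2), rownames(emb))
  quadrantOf <- function(size) {
    img <- rasterizeExpression(emb, v, width = size, height = size,
                               splatRadius = 0)
    on <- which(intensities(img) > 0, arr.ind = TRUE)
    paste(on[, 1] > size / 2, on[, 2] > size / 2)
  }
  q1 <- sort(table(quadrantOf(64)))
  q2 <- sort(table(quadrantOf(128)))
  expect_equal(names(q1), names(q2))
})

test_that("ncc satisfies self-match, affine invariance and symmetry", {
  set.seed(32)
  t1 <- matrix(runif(35), 7, 5)
  expect_equal(ncc(t1, t1), 1)
  expect_equal(ncc(t1, 2.5 * t1 + 3), 1)
  expect_equal(ncc(t1, -0.5 * t1 + 1), -1)
  p1 <- matrix(runif(35), 7, 5)
  expect_equal(ncc(t1, p1), ncc(p1, t1))
  expect_lte(abs(ncc(t1, p1)), 1)
  expect_message(z <- ncc(t1, matrix(1, 7, 5)), "zero-variance")
  expect_equal(z, 0)
  expect_error(ncc(t1, matrix(1, 5, 7)), "identical dimensions")
  expect_error(ncc(matrix(1, 1, 2), matrix(1, 1, 2)), "at least 4")
})

test_that("ncc equals the two-loop scalar oracle", {
  set.seed(33)
  for (i in 1:100) {
    h <- sample(2:9, 1); w <- sample(2:9, 1)
    if (h * w < 4) next
    a <- matrix(runif(h * w), h, w)
    b <- matrix(runif(h * w), h, w)
    expect_lt(abs(ncc(a, b) - scalarNCC(a, b)), 1e-10)
  }
})

.toyImageSet <- function(nGenes = 8, size = 48, seed = 34) {
  set.seed(seed)
  emb <- cbind(runif(100), runif(100))
  rownames(emb) <- sprintf("c%03d", 1:100)
  vals <- matrix(runif(nGenes * 100, 0, 2), nGenes,
                 dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                                 rownames(emb)))
  rasterizePanel(emb, vals, width = size, height = size)
}

test_that("fixed-mode search ranks the query gene first with score 1", {
  imgs <- .toyImageSet()
  q <- templateQuery("g03", 4, 4, 20, 20)
  hits <- templateSearch(q, imgs)
  expect_equal(hits$gene_id[1], "g03")
  expect_equal(hits$score[1], 1, tolerance = 1e-12)
  expect_true(all(diff(hits$score) <= 1e-12))
  expect_error(templateSearch(templateQuery("g03", 40, 40, 20, 20), imgs),
               "bounds")
  expect_error(templateSearch(templateQuery("nope", 0, 0, 8, 8), imgs),
               "not in image set")
})

test_that("fixed-mode scores are invariant to affine intensity rescaling", {
  imgs <- .toyImageSet()
  q <- templateQuery("g05", 2, 2, 24, 24)
  h1 <- templateSearch(q, imgs)
  scaled <- imgs
  scaled@intensities <- 0.4 * imgs@intensities + 0.1
  h2 <- templateSearch(q, scaled)
  expect_equal(h1$score, h2$score, tolerance = 1e-10)
})

test_that("slide mode recovers a planted translation exactly", {
  size <- 40
  img <- matrix(0, size, size)
  img[8:13, 6:12] <- matrix(runif(42, 0.5, 1), 6)
  shifted <- matrix(0, size, size)
  shifted[(8 + 2):(13 + 2), (6 + 3):(12 + 3)] <- img[8:13, 6:12]
  ints <- cbind(orig = as.vector(img), shift = as.vector(shifted))
  imgs <- new("ExpressionImageSet", intensities = ints,
              width = as.integer(size), height = as.integer(size),
              geneIds = c("orig", "shift"),
              provenance = list(splatRadius = 0, aggregation = "max",
                                scaleMax = 1))
  q <- templateQuery("orig", 5, 7, 9, 8, mode = "slide")
  hits <- templateSearch(q, imgs)
  hit <- hits[hits$gene_id == "shift", ]
  expect_equal(hit$score, 1, tolerance = 1e-8)
  expect_equal(hit$x0, 5 + 3)
  expect_equal(hit$y0, 7 + 2)
})

test_that("RGB composites invert domains onto a white background", {
  blank <- new("ExpressionImage", intensities = matrix(0, 8, 8),
               geneId = "a", provenance = list())
  comp <- compositeRGB(list(blank, blank))
  expect_true(all(comp == 1))

  left <- matrix(0, 8, 8); left[, 1:3] <- 1
  right <- matrix(0, 8, 8); right[, 6:8] <- 1
  ia <- new("ExpressionImage", intensities = left, geneId = "a",
            provenance = list())
  ib <- new("ExpressionImage", intensities = right, geneId = "b",
            provenance = list())
  comp2 <- compositeRGB(list(ia, ib))
  expect_equal(unname(comp2[1, 1, ]), c(0, 1, 1))   # pure cyan-ish channel
  expect_equal(unname(comp2[1, 7, ]), c(1, 0, 1))
  expect_equal(unname(comp2[1, 4, ]), c(1, 1, 1))   # background stays white

  grey <- compositeRGB(list(ia, ia, ia))
  expect_equal(grey[, , 1], grey[, , 2])
  expect_equal(grey[, , 2], grey[, , 3])
  expect_error(compositeRGB(list(ia)), "2 or 3")
})

test_that("rare-cell marker filter applies strict thresholds", {
  n <- 30
  m <- matrix(0, 4, n, dimnames = list(c("only", "boundary20", "value2",
                                          "common"),
                                       sprintf("c%02d", 1:n)))
  m["only", 1] <- 30                      # detected in exactly 1 cell
  m["boundary20", 1:20] <- 30             # detected in exactly 20 cells
  m["value2", 1] <- 30                    # will sit exactly at value 2
  m["common", ] <- 5
  norm <- logNormalize(m)
  norm["only", 1] <- 3
  norm["boundary20", 1] <- 3
  norm["value2", 1] <- 2                  # exactly at the threshold
  res <- rareCellMarkers(norm, "c01")
  expect_equal(res$gene_id, "only")
  expect_equal(res$n_cells_detected, 1L)

  # ordering is independent of gene and cell order
  sceN <- norm[sample(nrow(norm)), sample(ncol(norm))]
  res2 <- rareCellMarkers(sceN, "c01")
  expect_equal(res2$gene_id, res$gene_id)
  expect_error(rareCellMarkers(norm, "missing"), "unknown barcode")
})
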