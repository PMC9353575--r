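test_that("disc sampling handles empty and invalid inputs", {
  expect_equal(nrow(sampleDiscCells(0, seed = 1)), 0L)
  expect_error(sampleDiscCells(-5, seed = 1), "non-negative")
  expect_error(discGeometry(fracCM = 0.9, fracCumulus = 0.2), "sum")
})

test_that("disc sampling is deterministic and area-uniform", {
  a <- sampleDiscCells(500, seed = 42)
  b <- sampleDiscCells(500, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))

  big <- sampleDiscCells(20000, seed = 7)
  # closed form: E[r^2] = 1/2 for area-uniform sampling on the unit disc
  expect_lt(abs(mean(big$radius^2) - 0.5), 0.005)
  expect_true(all(big$radius >= 0 & big$radius <= 1))
  expect_true(all(big$angle >= 0 & big$angle < 2 * pi))

  ks <- suppressWarnings(
    stats::ks.test(sampleDiscCells(10000, seed = 3)$radius^2, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("subtype placement respects the layer structure", {
  tr <- sampleDiscCells(2000, seed = 5)
  expect_true(all(tr$layer[tr$subtype == "CM"] == "endoderm"))
  expect_true(all(tr$layer[tr$subtype == "cumulus"] == "endoderm"))
  rim <- tr[tr$subtype == "rim_intermediate", ]
  expect_true(all(rim$radius >= discGeometry()$rimCutoff))
  expect_true(all(tr$degGroup[tr$layer != "ectoderm"] == 0))
  expect_true(all(tr$degGroup[tr$layer == "ectoderm"] %in% c(-0.5, 0.5)))
})

test_that("spatial means follow the logistic domain model", {
  cellAt <- function(r) S4Vectors::DataFrame(
    cell_id = "c1", radius = r, angle = 0, layer = "ectoderm",
    subtype = "none", modality = "cell", degGroup = 0)
  per <- geneProgram("g", "peripheral", amplitude = 8, center = 0.6,
                     steepness = 10)
  # logistic midpoint: half amplitude exactly at the domain centre
  expect_equal(spatialMean(per, cellAt(0.6)), 4)
  sharp <- geneProgram("g", "peripheral", amplitude = 8, center = 0.6,
                       steepness = 1e6)
  expect_equal(spatialMean(sharp, cellAt(0.8)), 8, tolerance = 1e-9)
  expect_equal(spatialMean(sharp, cellAt(0.4)), 0, tolerance = 1e-9)

  cen <- geneProgram("g", "central", amplitude = 6, center = 0.3,
                     steepness = 12)
  expect_gt(spatialMean(cen, cellAt(0.1)), spatialMean(cen, cellAt(0.9)))

  emgCell <- S4Vectors::DataFrame(
    cell_id = "c1", radius = 0.1, angle = 0, layer = "endoderm",
    subtype = "emerging_posterior", modality = "cell", degGroup = 0)
  emg <- geneProgram("g", "emerging", amplitude = 2, center = 0.45,
                     nascentBoost = 3, target = "emerging_posterior")
  expect_equal(spatialMean(emg, emgCell, "nucleus") /
                 spatialMean(emg, emgCell, "cell"), 3)
})

test_that("gene program validation rejects inconsistent parameters", {
  expect_error(geneProgram("g", "peripheral", amplitude = 0), "positive")
  expect_error(geneProgram("g", "noise", amplitude = 1, dispersion = 0),
               "positive")
  expect_error(geneProgram("g", "peripheral", amplitude = 1,
                           nascentBoost = 2), "nascentBoost")
  expect_error(geneProgram("g", "peripheral", amplitude = 1,
                           steepness = Inf), "finite")
})

test_that("count simulation is deterministic and mean-faithful", {
  tr <- sampleDiscCells(200, seed = 2)
  panel <- smallPanel()
  a <- simulateCounts(tr, panel, seed = 9)
  b <- simulateCounts(tr, panel, seed = 9)
  expect_identical(as.matrix(SummarizedExperiment::assay(a, "counts")),
                   as.matrix(SummarizedExperiment::assay(b, "counts")))

  # Poisson limit: Monte-Carlo mean against the closed-form mean
  flat <- geneProgram("flat", "noise", amplitude = 5, dispersion = 4)
  manyCells <- sampleDiscCells(100000, seed = 3)
  sim <- simulateCounts(manyCells, flat,
                        depth = depthParams(sigma = 0), seed = 5,
                        poisson = TRUE)
  m <- mean(SummarizedExperiment::assay(sim, "counts")[1, ])
  expect_lt(abs(m - 5) / 5, 0.02)
})

test_that("depth scaling is linear and the nucleus modality is shallower", {
  tr <- sampleDiscCells(300, seed = 4)
  panel <- smallPanel()
  s1 <- simulateCounts(tr, panel, depth = depthParams(cellScale = 1),
                       seed = 6)
  s2 <- simulateCounts(tr, panel, depth = depthParams(cellScale = 2),
                       seed = 6)
  t1 <- mean(Matrix::colSums(SummarizedExperiment::assay(s1, "counts")))
  t2 <- mean(Matrix::colSums(SummarizedExperiment::assay(s2, "counts")))
  expect_lt(abs(t2 / t1 - 2), 0.1)

  for (s in 1:5) {
    cellMed <- median(Matrix::colSums(SummarizedExperiment::assay(
      simulateGermDisc(150, "cell", panel = panel, seed = s), "counts")))
    nucMed <- median(Matrix::colSums(SummarizedExperiment::assay(
      simulateGermDisc(150, "nucleus", panel = panel, seed = s), "counts")))
    expect_lt(nucMed, cellMed)
  }
})

test_that("peripheral and central genes have opposite radial trends", {
  sce <- smallSim(400, seed = 21)
  tr <- cellTruth(sce)
  counts <- SummarizedExperiment::assay(sce, "counts")
  fitSlope <- function(g) {
    fit <- summary(lm(as.numeric(counts[g, ]) ~ tr$radius))
    coef(fit)[2, c("Estimate", "Pr(>|t|)")]
  }
  per <- fitSlope("PER0001")
  cen <- fitSlope("CEN0004")
  expect_gt(per[1], 0); expect_lt(per[2], 0.01)
  expect_lt(cen[1], 0); expect_lt(cen[2], 0.01)
})

test_that("spiked QC outliers and doublets are appended and flagged", {
  tr <- sampleDiscCells(100, seed = 8)
  sce <- simulateCounts(tr, smallPanel(), seed = 8, nLowComplexity = 5,
                        nDoublets = 4)
  expect_equal(ncol(sce), 109)
  expect_equal(sum(cellTruth(sce)$qcClass == "low_complexity"), 5)
  expect_equal(sum(cellTruth(sce)$qcClass == "doublet"), 4)
})

test_that("counts round-trip exactly through the MTX writer and reader", {
  sce <- smallSim(120, seed = 31)
  dir <- withr::local_tempdir()
  writeCounts(sce, dir)
  back <- readCounts(dir, "mtx_triplet")
  m0 <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
  m1 <- as.matrix(SummarizedExperiment::assay(back, "counts"))
  expect_identical(m0, m1)
  # conservation: total equals the sum of per-gene totals
  expect_equal(sum(m1), sum(Matrix::rowSums(m1)))
})
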