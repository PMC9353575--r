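test_that("SNN clustering separates well-separated blobs exactly", {
  set.seed(1)
  # the neighbourhood must be large relative to the blob's internal
  # geometry, otherwise modularity optimisation subdivides dense blobs
  pts <- rbind(matrix(rnorm(100 * 2, 0, 0.1), ncol = 2),
               matrix(rnorm(100 * 2, 10, 0.1), ncol = 2))
  rownames(pts) <- sprintf("c%03d", 1:200)
  truth <- rep(0:1, each = 100)
  lab <- knnCluster(pts, k = 30, resolution = 0.5, seed = 3)
  expect_equal(length(unique(lab)), 2)
  expect_equal(mclust::adjustedRandIndex(lab, truth), 1)
  # determinism and size-ordered labels
  expect_identical(lab, knnCluster(pts, k = 30, resolution = 0.5, seed = 3))
  expect_equal(min(lab), 0L)

  same <- matrix(1, 50, 2, dimnames = list(sprintf("c%02d", 1:50), NULL))
  expect_equal(length(unique(knnCluster(same, k = 5, seed = 1))), 1)
  expect_error(knnCluster(pts, k = 400), "smaller")
})

test_that("rank-sum p-values match exact enumeration and wilcox.test", {
  # canonical hand case: complete separation of 3 vs 3
  expect_equal(rankSumTest(1:3, 4:6)$p, 0.1)

  set.seed(7)
  for (trial in 1:40) {
    nA <- sample(2:7, 1); nB <- sample(2:7, 1)
    x <- sample(0:5, nA, replace = TRUE)   # ties are frequent
    y <- sample(0:5, nB, replace = TRUE)
    expect_equal(rankSumTest(x, y)$p, enumRankSumP(x, y), tolerance = 1e-12)
    xc <- rnorm(nA); yc <- rnorm(nB)        # tie-free: compare to wilcox.test
    expect_equal(rankSumTest(xc, yc)$p,
                 wilcox.test(xc, yc, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }

  # large-sample normal path against the tie-corrected approximation
  set.seed(8)
  x <- rpois(60, 4); y <- rpois(50, 5)
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(rankSumTest(x, y)$p, ref, tolerance = 1e-10)
})

test_that("DEG testing controls its thresholds and ordering", {
  set.seed(9)
  base <- matrix(rpois(50 * 20, 3), nrow = 50,
                 dimnames = list(sprintf("g%02d", 1:50),
                                 sprintf("c%02d", 1:20)))
  norm <- logNormalize(base)
  # identical groups: nothing can be significant
  dup <- cbind(norm, norm)
  colnames(dup) <- sprintf("c%02d", 1:40)
  none <- wilcoxonDEG(dup, sprintf("c%02d", 1:20), sprintf("c%02d", 21:40))
  expect_equal(nrow(none), 0)
  expect_error(wilcoxonDEG(norm, "c01", c("c02", "c03")), "at least 2")
  expect_error(wilcoxonDEG(norm, c("c01", "c02"), c("c02", "c03")),
               "disjoint")
})

test_that("planted fold changes are recovered with controlled FDR", {
  recalls <- c(); fdrs <- c()
  for (s in 1:5) {
    set.seed(s)
    nG <- 1000; nPer <- 100
    mu <- runif(nG, 1, 8)
    shifted <- 1:50
    a <- matrix(rnbinom(nG * nPer, mu = mu, size = 4), nrow = nG)
    muB <- mu; muB[shifted] <- muB[shifted] * 2
    b <- matrix(rnbinom(nG * nPer, mu = muB, size = 4), nrow = nG)
    m <- cbind(a, b)
    dimnames(m) <- list(sprintf("g%04d", 1:nG), sprintf("c%03d", 1:(2 * nPer)))
    # equal-depth design: log1p counts are a valid normalised matrix and
    # keep the null genes free of depth-compensation shifts
    deg <- wilcoxonDEG(log1p(m), sprintf("c%03d", 1:nPer),
                       sprintf("c%03d", (nPer + 1):(2 * nPer)),
                       alpha = 0.05, minAbsLFC = 0.25)
    hits <- match(deg$gene_id, rownames(m))
    recalls <- c(recalls, mean(shifted %in% hits))
    fdrs <- c(fdrs, if (nrow(deg) > 0) mean(!(hits %in% shifted)) else 0)
  }
  expect_gte(mean(recalls), 0.9)
  expect_lte(mean(fdrs), 0.1)
})

test_that("BH adjustment preserves the order of raw p-values", {
  set.seed(10)
  p <- runif(200)^2
  adj <- p.adjust(p, "BH")
  expect_true(all(adj >= p - 1e-15))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-15))
})

test_that("Ward clustering matches hand-checkable geometry", {
  two <- matrix(c(0, 0, 3, 4), nrow = 2, byrow = FALSE,
                dimnames = list(c("g1", "g2"), c("a", "b")))
  hc <- wardHierarchy(two)
  expect_equal(hc$height, 5)           # single merge at the distance

  quad <- t(matrix(c(0, 0, 0, 1, 10, 0, 10, 1), ncol = 2, byrow = TRUE,
                   dimnames = list(c("a", "b", "c", "d"), c("g1", "g2"))))
  hcq <- wardHierarchy(quad)
  expect_equal(sort(hcq$height[1:2]), c(1, 1))
  expect_gt(hcq$height[3], 10)
  # the two close pairs merge first
  cut2 <- cutree(hcq, 2)
  expect_equal(cut2[["a"]], cut2[["b"]])
  expect_equal(cut2[["c"]], cut2[["d"]])

  expect_error(wardHierarchy(two[, 1, drop = FALSE]), "at least 2")
  nwk <- linkageToNewick(hcq)
  expect_match(nwk, "^\\(.*\\);$")
})

test_that("Ward linkage equals the naive O(n^3) oracle", {
  set.seed(11)
  for (trial in 1:30) {
    n <- sample(4:8, 1)
    pts <- matrix(rnorm(n * 3), nrow = n)
    rownames(pts) <- sprintf("c%d", seq_len(n))
    hc <- hclust(dist(pts), method = "ward.D2")
    oracle <- naiveWard(pts)
    expect_equal(sort(hc$height), sort(oracle$heights), tolerance = 1e-8)
    expect_equal(as.matrix(cophenetic(hc))[rownames(pts), rownames(pts)],
                 `dimnames<-`(oracle$cophenetic,
                              list(rownames(pts), rownames(pts))),
                 tolerance = 1e-8)
  }
})

test_that("cluster markers recover planted layer identities", {
  sce <- smallSim(400, seed = 22)
  tr <- cellTruth(sce)
  norm <- logNormalize(SummarizedExperiment::assay(sce, "counts"))
  labels <- setNames(match(tr$layer,
                           c("ectoderm", "mesoderm", "endoderm")) - 1L,
                     tr$cell_id)
  mk <- clusterMarkers(norm, labels)
  expect_setequal(names(mk), c("0", "1", "2"))
  expect_true(all(grepl("^MKECT", mk[["0"]]$gene_id[1:3])))
  expect_true(all(grepl("^MKMES", mk[["1"]]$gene_id[1:3])))
  expect_true(all(grepl("^MKEND", mk[["2"]]$gene_id[1:3])))

  # invariance to cell-order permutation
  perm <- sample(ncol(norm))
  mkp <- clusterMarkers(norm[, perm], labels[colnames(norm)[perm]])
  expect_equal(mk[["0"]]$gene_id, mkp[["0"]]$gene_id)

  single <- setNames(rep(0L, ncol(norm)), colnames(norm))
  expect_equal(length(clusterMarkers(norm, single)), 0)
})

test_that("the exclusion loop leaves an artifact-free dataset untouched", {
  panel <- defaultPanel(nPolarityEach = 6, nUbiquitous = 40,
                        nLayerMarkers = 8, nCMMarkers = 0,
                        nCumulusMarkers = 0, nEmerging = 0, nNoise = 60,
                        degGroupEffect = 0)
  sce <- simulateGermDisc(500, panel = panel, seed = 15)
  res <- exclusionRecluster(sce, polarityPanelGenes(panel),
                            nVarGenes = 100, nPcs = 10, seed = 15)
  expect_equal(length(res$excluded), 0)
})
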