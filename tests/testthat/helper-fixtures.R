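# Shared fixtures, computed lazily and cached for the whole test run.
# The "default disc" (2,000 cells, full default panel, seed 1) is the
# standard study condition used by several end-to-end tests; smaller
# panels keep unit tests fast.

.fixtures <- new.env(parent = emptyenv())

memoFixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

smallPanel <- function() {
  defaultPanel(nPolarityEach = 4, nUbiquitous = 20, nLayerMarkers = 5,
               nCMMarkers = 3, nCumulusMarkers = 2, nEmerging = 2,
               nNoise = 30)
}

smallSim <- function(n = 300, seed = 11) {
  memoFixture(paste0("smallSim_", n, "_", seed),
              simulateGermDisc(n, panel = smallPanel(), seed = seed))
}

defaultSim <- function() {
  memoFixture("defaultSim", simulateGermDisc(2000, seed = 1))
}

defaultNorm <- function() {
  memoFixture("defaultNorm", logNormalize(
    SummarizedExperiment::assay(defaultSim(), "counts")))
}

defaultExclusion <- function() {
  memoFixture("defaultExclusion", exclusionRecluster(
    defaultSim(), polarityPanelGenes(genePanel(defaultSim())), seed = 1))
}

# Naive O(n^3) Ward (ward.D2) oracle: greedy merging on the exact Ward
# distance recomputed from cluster centroids at every step. Returns merge
# heights and the cophenetic distance matrix.
naiveWard <- function(pts) {
  n <- nrow(pts)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1)
  coph <- matrix(0, n, n)
  wardDist <- function(a, b) {
    ca <- colMeans(pts[a, , drop = FALSE])
    cb <- colMeans(pts[b, , drop = FALSE])
    na <- length(a); nb <- length(b)
    sqrt(2 * na * nb / (na + nb) * sum((ca - cb)^2))
  }
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestD <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        d <- wardDist(clusters[[i]], clusters[[j]])
        if (d < bestD) { bestD <- d; best <- c(j, i) }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- bestD; coph[b, a] <- bestD
    heights[step] <- bestD
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  list(heights = heights, cophenetic = coph)
}

# toy count matrix with prescribed per-cell totals (10 genes per cell)
.toyCounts <- function(totals) {
  m <- sapply(totals, function(t) {
    v <- rep(floor(t / 10), 10)
    v[1] <- v[1] + t - sum(v)
    v
  })
  dimnames(m) <- list(sprintf("g%02d", 1:10),
                      sprintf("cell%02d", seq_along(totals)))
  m
}

# two-loop scalar reference for the normalised correlation coefficient
scalarNCC <- function(tmpl, patch) {
  tb <- mean(tmpl); pb <- mean(patch)
  num <- 0; dt <- 0; dp <- 0
  for (i in seq_len(nrow(tmpl))) {
    for (j in seq_len(ncol(tmpl))) {
      num <- num + (tmpl[i, j] - tb) * (patch[i, j] - pb)
      dt <- dt + (tmpl[i, j] - tb)^2
      dp <- dp + (patch[i, j] - pb)^2
    }
  }
  if (dt == 0 || dp == 0) return(0)
  num / sqrt(dt * dp)
}

# brute-force two-sided rank-sum p-value by enumeration over index subsets
enumRankSumP <- function(x, y) {
  nA <- length(x); n <- nA + length(y)
  r <- rank(c(x, y))
  mu <- nA * (n + 1) / 2
  dev <- abs(sum(r[seq_len(nA)]) - mu)
  idx <- utils::combn(n, nA)
  hits <- 0
  for (k in seq_len(ncol(idx))) {
    if (abs(sum(r[idx[, k]]) - mu) >= dev - 1e-9) hits <- hits + 1
  }
  hits / ncol(idx)
}

# majority-vote cluster -> layer mapping followed by the adjusted Rand
# index against the true layers
layerARI <- function(labels, truth) {
  layers <- truth[names(labels), "layer"]
  maj <- tapply(layers, labels, function(x) names(which.max(table(x))))
  mapped <- unname(maj[as.character(labels)])
  mclust::adjustedRandIndex(mapped, layers)
}
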