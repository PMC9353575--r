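---
title: "Reconstructing germ-disc polarity from dissociated cells: models and methods"
author: "scPolarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing germ-disc polarity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

At the late germ-disc stage, a spider embryo is a disc of roughly 2,000
morphologically uniform epithelial cells. The disc centre corresponds to
the future posterior pole and the rim to the future anterior, so the
radial coordinate of a cell *is* its prospective anterior–posterior (A–P)
address. Positional identity along this axis is encoded in concentric,
partially overlapping expression domains of Hedgehog-signalling target
genes whose boundaries are fuzzy rather than sharp. Dissociating the
tissue for single-cell or single-nucleus RNA-seq destroys all spatial
information; the computational question is whether, and how reliably, the
radial (A–P) organisation, the three germ layers, and rare cell
populations can be reconstructed purely from the dissociated expression
profiles.

scPolarity implements a complete, testable pipeline for this problem: a
generative simulator of the germ disc that provides per-cell ground truth,
the standard preprocessing tower (QC, log-normalisation, variable
features, PCA, SNN graph clustering), a differential-expression-driven
artifact-removal loop, quantitative polarity-axis reconstruction, an
expression-image similarity search, and a rare-cell marker filter. Because
every simulated cell carries its true radius, layer and subtype, every
downstream claim is scored against ground truth rather than inspected by
eye.

## The generative model

### Geometry and cell types

Cell positions are sampled uniformly over the unit disc
(`radius = sqrt(U)`, so radius² ~ Uniform(0,1) — a property the test suite
checks with a Kolmogorov–Smirnov test). Germ layers follow radial
cutoffs: endoderm below radius 0.45 (~20% of cells), mesoderm above 0.85
(the internalising rim, ~28%), ectoderm in between. Within the eligible
pools we plant rare subtypes:

* **CM cells** (default 0.5%, i.e. ~10 of 2,000): cumulus mesenchymal
  cells near the disc centre, endodermal by construction.
* **cumulus cells** (2%): central endodermal cells responding to CM
  signals, marked by their own small gene module.
* **emerging_posterior cells** (5%): central endodermal cells in a
  nascent transcriptional state, detectable mainly through nuclear
  (pre-mRNA-rich) profiles.
* **rim_intermediate cells** (2%): cells just outside the rim cutoff
  captured mid-way through ectoderm-to-mesoderm internalisation; they
  express both ectodermal and mesodermal markers at half amplitude.

### Gene programs

Each gene follows one of eight response classes (`geneProgram()`):
logistic radial responses for `peripheral`, `central` and `intermediate`
genes — e.g. a peripheral gene has expectation
`A * s(k (r − c))` with logistic `s`, amplitude `A` (molecules at full
activation), steepness `k` (the single boundary-fuzziness knob; smaller
`k` = fuzzier, more overlapping domains) and domain centre `c` — plus
on/off `layer_marker` and `rare_marker` classes, a `ubiquitous_deg`
artifact class, nucleus-sensitive `emerging` genes, and flat low-level
`noise` genes. Counts are negative binomial with per-gene dispersion
(`size`; `Inf` selects the Poisson limit used by closed-form oracle
tests) and lognormal per-cell size factors (sd 0.25). The nucleus
modality captures one third of the cell modality's molecules.

The default panel holds 48 polarity genes (16 per radial class, centres
spread so neighbouring domains overlap), 400 ubiquitous artifact genes,
30 markers per germ layer, 9 CM markers, 6 cumulus markers, 4 emerging
genes and 1,500 noise genes (~2,060 genes total, per-cell depth around
4,000 molecules).

### The clustering artifact

In the real experiment the ectoderm split into two large clusters that
exhibited identical spatial polarity; the genes separating them were
expressed ubiquitously and at levels an order of magnitude above the
average gene, and excluding them merged the spurious pair. The simulator
reproduces this: every ectodermal cell is assigned a random artifact
group (±0.5, non-ectodermal cells 0), and each of the 400 ubiquitous
genes carries a signed log-scale offset between the groups (magnitudes
0.54–1.26, alternating sign across the panel).

Two details matter and were chosen deliberately:

* **Signed, per-gene offsets.** If all artifact genes shifted in the same
  direction by the same amount, per-cell depth normalisation would cancel
  the artifact exactly (the artifact genes dominate the library) and it
  would resurface as a spurious compensatory shift in every *other* gene.
  Balanced signs keep the artifact in the artifact genes, where it
  belongs.
* **Symmetric ±0.5 group coding.** With 0/1 coding the "up" group would
  carry `cosh(m)` ≈ 1.4× more ubiquitous molecules purely by convexity of
  the exponential, so normalisation would again couple the artifact to
  every other gene. Symmetric coding equalises the two halves' expected
  library sizes.

### What the simulator does not model

No UMI collisions, ambient RNA, batch effects, read-level noise, doublet
transcriptional interaction (doublets are plain sums), cell-cycle
structure, or any attempt to match a specific deposited dataset
numerically. Passing tests demonstrate that the *methods* behave as
specified under a controlled, realistic noise model — not that any
particular biological dataset will reach the same scores.

## Preprocessing choices

* **QC.** Two filter rules: an absolute window on detected genes with a
  strict molecule ceiling, and a mode-relative band keeping cells with
  50%–200% of the modal library size. "The mode" of a quasi-continuous
  total-count distribution is not well defined; we use the centre of the
  most populated fixed-width histogram bin (default width 100), breaking
  ties toward the lower bin, and record the bin width and computed mode in
  the QC report. The molecule ceiling is exclusive (`< max`), following
  the usual "fewer than N molecules" phrasing.
* **Normalisation.** `ln(1 + count · 10⁴ / total)`; the scale factor
  10,000 and the scaled-value clip at ±10 follow the de-facto defaults of
  the standard single-cell toolkits, and both are arguments.
* **Variable features.** Standardised dispersion (variance/mean z-scored
  within 20 mean-expression bins); bins with fewer than two genes or zero
  spread fall back to a global z-score so that a single outlying gene is
  still ranked first.
* **PCA.** Exact SVD by default so results are bit-reproducible; a seeded
  randomised subspace solver is available for large matrices. Component
  signs follow the "largest-magnitude loading positive" convention.
  Zero-variance genes are dropped with a message (their z-score is
  undefined).

## Clustering and the DEG-exclusion loop

Clustering builds a k-nearest-neighbour graph (k = 20, Euclidean in PC
space, neighbourhoods include the cell itself), re-weights edges by the
Jaccard similarity of neighbour sets, prunes below 1/15, and runs Louvain
modularity optimisation at a chosen resolution. Labels are re-indexed by
decreasing cluster size.

`exclusionRecluster()` automates the artifact-removal procedure that was
performed by inspection in the original analysis:

1. run the standard pipeline and cluster;
2. find the *candidate spurious pair*: the largest pair of clusters whose
   centroid profiles over the 48-gene polarity panel are near-parallel.
   We use the cosine of **mean-centred** profiles (equivalently, Pearson
   correlation, threshold 0.9). Raw cosines of all-positive expression
   profiles are inflated — ectoderm vs mesoderm already reaches ~0.8 —
   whereas centring separates true artifact halves (≈ 1.0) from distinct
   tissues (≤ ~0.65). An explicit cluster pair can be supplied to
   override the detector;
3. test the pair with the Wilcoxon DEG machinery (fold-change floor 0.4
   natural-log units in this loop — above the ≤ ~0.3 incidental
   composition differences between halves of one tissue, below the
   ≥ 0.54 planted artifact offsets);
4. check that the DEG set is *dominated by highly expressed genes*: its
   median per-gene total count must exceed the 80th percentile of all
   working genes (echoing the order-of-magnitude expression gap of such
   artifacts); only then are the DEGs excluded and the loop repeated
   (at most 3 exclusion rounds).

Exclusion removes the genes from variable-feature selection, PCA and
subsequent DEG testing; library-size normalisation still uses all genes,
mirroring exclusion "from downstream analyses" rather than
re-quantification.

The Wilcoxon rank-sum test is implemented in the package: exact
enumeration of all group assignments when both groups have ≤ 10 cells
(two-sided p = probability of a rank-sum at least as far from its null
mean as observed, which remains well defined under ties), otherwise the
normal approximation with tie correction and no continuity correction.
Fold changes are computed in de-logged (expm1) space with a pseudocount
of 1 on both sides. Ward clustering of cells over marker panels uses
`hclust`'s ward.D2 (squared-distance Ward); the test suite verifies it
against a naive O(n³) re-computation of the Ward objective from cluster
centroids.

## Polarity reconstruction and scoring

The polarity axis of a cell subset is the first principal axis of its 2D
embedding. The default embedding for quantitative work is `pc12` (the
first two PCs verbatim) because it is deterministic and
solver-independent; a seeded UMAP is available for visualisation. Since
dissociation destroys orientation, the axis sign is arbitrary and all
agreement statistics use absolute correlations: |Spearman| between axis
and true radius per cell, and |Kendall tau| between cluster-centroid
order along the axis and cluster mean-radius order.

Under the default conditions (2,000 cells, PCA restricted to the 48
polarity genes, ectodermal cells), the suite requires |Spearman| ≥ 0.7
and a perfect tau over four radius-quartile annuli; the observed
|Spearman| is around 0.97, i.e. the fuzzy-domain code is easily rich
enough to linearise the radial axis.

## Expression images and template matching

`rasterizePanel()` renders every gene on the shared embedding: linear
mapping with a 5% margin, each cell splatting a disc of radius 2 pixels,
overlaps combined by max. Pixels with no cell are exactly 0 — the
background equals the colour of non-expressing cells, which is what makes
correlation-based matching of expression domains meaningful. Intensities
are normalised by a single panel-wide constant (the 99th percentile of
rendered values) so ubiquitous dim genes cannot mimic patterned ones;
per-gene normalisation is a flag. The similarity score is the normalised
correlation coefficient; fixed-location matching (comparing "the
corresponding area" of every gene's plot) is the default, with a sliding
search (FFT cross-correlation numerator, integral-image local variances)
available. Zero-variance patches score 0 by convention. Composites invert
each image (white background) and assign channels.

Numerical choices: the default raster is 256×256; the packaged
whole-panel analyses use 128×128, which keeps a ~2,000-gene image set
around 270 MB and renders in seconds without changing retrieval results.

## Rare-cell markers

`rareCellMarkers()` reproduces the single-cell marker filter: genes with
normalised value > 2 in one chosen cell and detected (value > 0, i.e. at
least one molecule) in strictly fewer than 20 cells, ranked by the value
in the target cell. Both thresholds are strict inequalities and the test
suite pins the boundary cases (value exactly 2; detected in exactly 20
cells). The target cell is identified the way it was in the original
analysis: the cell with the strongest expression of a known lead marker.

## Modality sensitivity

Emerging genes model transcriptional programs that have just switched on:
their transcripts are predominantly nascent and nuclear. In the simulator
they are restricted to the `emerging_posterior` subtype, with amplitude
0.6 molecules per gene in whole-cell profiles and a nucleus-side nascent
boost of 6. The boost must exceed the inverse nucleus depth fraction (3)
to carry information: at boost 3 a nucleus contains exactly as many
molecules of the gene as a cell does, and after per-gene standardisation
the two modalities cluster identically. At boost 6 a nucleus carries
twice the molecules against one third of the background, and the packaged
analysis (800 cells per modality, matched Louvain resolution 2.0, seed
pairs) detects the emerging cluster (purity ≥ 0.7) in nucleus mode but
not in cell mode in the large majority of seed pairs — the simulated
counterpart of nucleus profiling revealing dynamic cell states that
whole-cell profiling merges away.

## Reproducibility and problem sizes

Every stochastic stage takes an explicit seed; `runPipeline()` derives
per-stage seeds from one global seed and records them in a provenance
JSON, and re-running a configuration reproduces every output
byte-for-byte. The packaged analyses use the study-scale default of
2,000 cells for polarity, layer separation, template retrieval and rare
markers, and 800 cells per modality across 10 seed pairs for the
cell/nucleus comparison; these sizes were fixed once as the package's
standard conditions and are arguments everywhere.

## Interface note

The package is organised as a Bioconductor-style library driven from R:
`SingleCellExperiment` is the count container, S4 classes with validity
methods carry images and polarity reports, and the pipeline is composed
of exported functions (`simulateGermDisc()`, `qcFilter()`,
`logNormalize()`, `exclusionRecluster()`, `polarityScore()`,
`templateSearch()`, `rareCellMarkers()`, `runPipeline()`); configuration
files (YAML) and the run-directory layout provide the batch interface
that a shell CLI would otherwise cover.

## Known limitations

* The simulator's fuzziness, amplitudes and rare-type frequencies are
  plausibility choices, not fits to measured data; absolute scores on
  real datasets will differ.
* The spurious-pair detector assumes the artifact splits the *largest*
  similarly-polarised pair; pathological datasets with several parallel
  splits may need the explicit `pair` override.
* The polarity axis is a single straight line in embedding space; curved
  manifolds (horseshoe-shaped embeddings) would need a principal curve,
  which is out of scope.
* Sliding template search is exhaustive per gene and is intended for
  single queries, not whole-panel scans.
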