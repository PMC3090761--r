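---
title: "Spectral clustering of expression time courses: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral clustering of expression time courses: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneEigenmaps)
```

## The problem

A developmental time course measured on expression microarrays yields,
after summarization, a matrix of $n$ genes by $D$ time points; each gene
is a vector $x_i \in \mathbb{R}^D$. Genes participating in a common
regulatory program co-vary over time, but the geometry of those
co-variation patterns need not be linear: projections of real
time-course data often show curved, cone-like sheets rather than linear
subspaces. This package clusters genes after a *nonlinear* spectral
embedding of the expression vectors, optionally steered by a small set
of labeled genes, and scores the resulting clusters by gene-set
overrepresentation.

## The model

**Graph construction.** Nodes are genes; $i$ and $j$ are connected when
$x_i$ is among the $m$ nearest neighbors of $x_j$ or vice versa
(Euclidean metric). Edges carry heat-kernel weights

$$W_{ij} = \exp\left(-\lVert x_i - x_j\rVert^2 / \sigma\right),$$

with bandwidth $\sigma$. The diagonal degree matrix
$D_{ii} = \sum_j W_{ij}$ measures each gene's total connection strength
and doubles as a *connectivity score*: genes with unusually high degree
are network hubs.

**Laplacian Eigenmaps (LE).** With $L = D - W$, the embedding minimizes
$\sum_{ij} W_{ij}\lVert y_i - y_j \rVert^2 = \mathrm{tr}(y^\top L y)$
subject to $y^\top D y = I$, solved by the eigenvectors of the
generalized problem $Lx = \lambda Dx$ with the $d$ smallest non-trivial
eigenvalues. We work through the change of variables $z = D^{1/2}y$,
which gives an ordinary symmetric eigenproblem on
$D^{-1/2} L D^{-1/2}$; the orthonormal $z$ automatically yield
$y^\top D y = I$. For a connected graph the constant vector is the only
eigenvector with eigenvalue 0 and is excluded.

**Schroedinger Eigenmaps (SE).** Prior knowledge enters as a label set
$S$ (here: connectivity hubs). $L$ is replaced by $E = L + \alpha V$,
where $V$ is the Laplacian of the complete unit-weight graph on $S$, so
that $y^\top V y = \sum_{i<j \in S} (y_i - y_j)^2$. The potential
penalizes spread among labeled genes: as $\alpha$ grows the labeled
genes contract toward a common location, dragging their graph
neighborhoods along. $\alpha = 0$ recovers LE exactly — a regression
test asserts equality to $10^{-10}$. Among the potential forms
compatible with "labeled points are forced closer", we chose the
attractive clique form because it is symmetric positive semidefinite,
annihilates constants (so the trivial mode is unchanged), and has a
single interpretable strength parameter; diagonal "barrier" potentials
were considered and not implemented.

**Clustering and model selection.** k-means (Lloyd's algorithm) runs on
the embedded coordinates with squared-Euclidean assignment; the same
squared distance is used by the silhouette coefficient
$\mathrm{sil}(x) = (B - A)/\max(A, B)$, where $A$ is the mean squared
distance to co-members and $B$ the minimum over other clusters of the
mean squared distance to that cluster. Across random restarts the run
with the *maximal overall silhouette* is kept — not the minimal
within-cluster sum of squares; both are recorded. The neighbor count
$m$ and target dimension $d$ are swept over a grid and the cell with the
best silhouette wins, ties resolved toward smaller $d$, then smaller
$m$ (parsimony).

**Enrichment.** Each (cluster, category) pair is tested with the
one-sided Fisher / hypergeometric upper tail
$P(X \ge \text{overlap})$, and Benjamini–Hochberg q-values are computed
within each cluster's family of categories (a pooled, global-family mode
is also available; the choice is reported with the results). The
universe defaults to the clustered genes intersected with the union of
the gene-set members, and categories with fewer than 2 members after
intersection are skipped.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `m` | 10 | neighbor count; controls sparsity of $W$ and graph connectivity. Swept over `5:10, 12, 15, 20, 25, 50, 100` by default. |
| `d` | 2 | target dimension; swept over `1:10, 12, 16` by default. |
| `sigma` | 1/8 | heat-kernel bandwidth, in squared log2-expression units. Presumes profiles on a normalized (log) scale; see below. |
| `alpha` | 1 | SE potential strength, dimensionless; 0 = unsupervised. Co-clustering of labels saturates for large `alpha` (the hub experiments use 100). |
| `k` | 24 | cluster count; k-means requires it a priori. |
| `nRestarts` | 100 | k-means restarts; restart seeds are `seed + 0 .. seed + nRestarts - 1`. |
| `foldLow`, `foldHigh` | 4, 26 | inclusive fold-change window (max/min over the course); on log2 data the ratio is `2^(max - min)`. |
| `beta` | 6 | soft power for the unsigned correlation connectivity; the usual convention for unsigned co-expression networks. Automatic soft-threshold selection is out of scope. |
| `hubCount` | 5 (degree) / 7 (correlation) | labeled hubs for SE. |
| FDR thresholds | 0.05, 0.10, 0.15, 0.20 | reporting grid for enriched-category counts. |

**Why log2 before embedding.** With $\sigma = 1/8$ fixed, distances must
be on a scale where near neighbors are a fraction of a unit apart. On
linear intensities (hundreds to tens of thousands) every weight
underflows to zero. `runPipeline()` therefore log2-transforms
linear-scale input by default (`logTransform = TRUE`), and the
fold-change filter always operates on the linear scale before the
transform.

## Numerical choices

- **Trivial-mode removal by counting, not thresholding.** On a connected
  graph the null space of $L + \alpha V$ is exactly the constant vector
  ($V$ annihilates constants too), so the engine drops exactly one
  smallest eigenpair. A magnitude threshold was tried first and fails
  when a strong potential stretches the spectrum across many orders of
  magnitude.
- **Eigensolver.** Dense `eigen(symmetric = TRUE)` up to 800 nodes;
  ARPACK (smallest-algebraic, via igraph) above, with a dense fallback
  on non-convergence. Both paths are checked against an independent
  dense generalized-eigenproblem oracle in the tests.
- **Sign convention.** Each eigenvector column has its
  largest-magnitude entry made positive (first index on ties), making
  embeddings reproducible across platforms.
- **Neighbor ties** break by (distance, gene index); **assignment ties**
  in k-means go to the lowest cluster index; an **emptied cluster** is
  re-seeded at the point farthest from its assigned centroid (distinct
  points when several clusters empty at once). All three rules are
  deterministic.
- **Singleton silhouette** is defined as 0; two coincident clusters give
  non-positive silhouettes (both standard conventions; degenerate
  configurations then cannot look artificially good).
- **Disconnected graphs** are a hard error with an advisory to raise
  `m`; `largestComponent = TRUE` embeds the largest component and
  reports dropped genes instead.
- **Randomness** flows from a single integer seed; generators save and
  restore the caller's RNG state.

## What the synthetic generators emulate

`generateClusteredProfiles()` builds a time-course matrix the shape of a
small microarray study: smooth random-walk template profiles per
cluster, per-gene Gaussian noise in log2 space, an anti-correlated
"repressed" cluster (the negation of cluster 1's template), a 3-gene
outlier group with a distinct spike profile, designated hub genes with
strongly reduced noise (hence maximal within-cluster correlation), and
per-gene fold changes placed inside the filter window by construction.
`generateTwoCones()` samples two side-by-side cone surfaces (uniform in
height and angle, apex separation twice the base radius) rotated into 8
dimensions — a curved benchmark for nonlinear-versus-linear embeddings.
`generateLatentBlobs()` plants Gaussian clusters in a 2-D latent plane
rotated into 8 dimensions, the fixture for dimension-selection checks.

What they do *not* emulate: probe-level noise models, normalization
artifacts, missing values, heavy-tailed intensity distributions, or the
correlated noise structure of real arrays. Passing tests on these
fixtures demonstrates that the machinery recovers structure it is
designed for, not that it will resolve any particular real data set.

## Design decisions on open points

- **Fold-change operator**: max/min across the whole course, bounds
  inclusive; on log2 data $2^{\max - \min}$. The upper bound default is
  26 as commonly printed for this kind of window; it is a plain
  parameter (`foldHigh`) because a reading of 2^6 = 64 is also
  defensible.
- **Restart selection by silhouette** (not SSE): applied uniformly to
  all embedding arms, including the PCA and raw-vector baselines.
- **FDR family**: per-cluster by default, global pooling by option; a
  resampling-based FDR was rejected as non-deterministic.
- **Two-cluster comparisons** between embedding arms follow each
  method's own dimension-selection rule: LE takes the
  silhouette-selected $(m, d)$ and PCA retains components covering 85%
  of variance.

## Problem sizes used by the tests and the acceptance script

Oracle checks run on 20–60-node graphs (50 instances), 100 random
silhouette instances, and every hypergeometric configuration up to a
200-gene universe on a fixed grid. Pipeline-level checks use 500-point
two-cones data over 10 seeds, 120-gene planted profiles over 10 seeds,
and 150-point latent blobs over 5 seeds with 5–20 k-means restarts.
These sizes were chosen so the whole suite documents the method's
behavior at desk scale; the algorithms themselves are routinely used at
$n$ in the thousands.

## Known limitations

- **Silhouette-based dimension selection is biased toward small $d$.**
  With squared-Euclidean silhouettes, adding a coordinate inflates
  within-cluster spread ($A$) at least as fast as between-cluster
  separation ($B$) on smooth manifolds, so $d = 1$ wins whenever one
  spectral coordinate already separates the clusters. The sweep
  recovers $d = 2$ on fixtures whose cluster-indicator eigenspace is
  exactly two-dimensional (e.g. three well-separated blobs); on
  continuum data the selected $d$ should be read as "smallest dimension
  with adequate cluster structure", not as an intrinsic-dimension
  estimate.
- **Linearly separable class structure favors linear baselines.** Two
  disjoint convex point clouds (such as side-by-side cones) are
  separated by PCA + k-means essentially optimally; the nonlinear arm
  matches but cannot exceed it there. The nonlinear advantage the
  method is designed for concerns interleaved or curved class
  boundaries.
- **Correlation-based hub scores on 8 time points are noisy**: sample
  correlations carry sampling error that compresses the contrast
  between designated hubs and their neighbors, especially at low noise
  where all profiles are near their template. Degree-based scores are
  the more stable labeling source at this series length.
- k is fixed a priori; no gap statistic or similar selection is
  provided. GO-DAG propagation and category pruning are out of scope
  for the enrichment stage.
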