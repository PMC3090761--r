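# geneEigenmaps

Semi-supervised spectral clustering of gene expression time courses.

Developmental time-course experiments summarize to a genes-by-time-points
matrix in which co-regulated genes trace similar — but often nonlinearly
arranged — trajectories. `geneEigenmaps` clusters such data after a
nonlinear spectral embedding instead of clustering raw vectors or PCA
scores, and can steer the embedding with a handful of labeled genes
(typically network hubs), for analysts who want cluster structure that
linear projections miss and a deterministic, fully scripted pipeline from
expression TSV to enrichment table.

## The method

1. **Graph**: connect genes that are mutual candidates among each
   other's *m* nearest neighbors (Euclidean metric on expression
   profiles); weight edges with the heat kernel
   *W<sub>ij</sub>* = exp(−‖x<sub>i</sub> − x<sub>j</sub>‖²/σ).
2. **Laplacian Eigenmaps**: with degree matrix *D* and *L = D − W*,
   embed genes by the eigenvectors of the *d* smallest non-trivial
   generalized eigenvalues of *Lx = λDx* (constraint *yᵀDy = I*,
   constant mode excluded).
3. **Schroedinger Eigenmaps** (semi-supervised): replace *L* with
   *E = L + αV*, where *V* is an attractive clique potential on a
   labeled gene set — labeled genes are pulled together as α grows;
   α = 0 recovers step 2 exactly. Labels come from a file or from
   connectivity scores (weighted degree, or |cor|^β co-expression
   connectivity).
4. **Clustering**: k-means (squared-Euclidean, Lloyd) with best-of-*N*
   restarts selected by the maximal overall silhouette coefficient
   (also squared-Euclidean); *m* and *d* are chosen by a silhouette
   sweep. Average-linkage hierarchical clustering and an adjusted-Rand
   utility are included.
5. **Enrichment**: one-sided Fisher (hypergeometric upper-tail) test of
   every cluster against a GMT gene-set collection, Benjamini–Hochberg
   FDR per cluster (or pooled), with enriched-category counts at
   0.05/0.10/0.15/0.20.

Synthetic generators with planted ground truth (clustered time-course
profiles with hubs and an anti-correlated cluster, two side-by-side cone
surfaces, latent-plane Gaussian blobs) make every stage testable end to
end. See the vignette in `vignettes/spectral-gene-clustering.Rmd` for
models, parameter meanings and design decisions.

## Worked example

```r
library(geneEigenmaps)

sim <- generateClusteredProfiles(nGenes = 120, nClusters = 6,
                                 noiseSd = 0.1, seed = 1)
em  <- logTransform(foldChangeFilter(sim$matrix, 4, 26))
emb <- laplacianEigenmaps(em, m = 40, d = 6, sigma = 4)
emb
#> GeneEmbedding (laplacian): 120 genes x 6 dimensions
#> eigenvalues: 0.00027854, 0.0060081, 0.27424, 0.42156, 0.94936, 0.96814

cl <- bestKMeans(emb, k = 7, nRestarts = 20, seed = 1)
cl
#> GeneClustering: 120 genes in 7 clusters (objective 0.01836)
#> overall silhouette 0.8482 (20 restarts)

adjustedRandIndex(clusterAssignment(cl), sim$truth$true_cluster)
#> [1] 0.847542

enr <- enrichAllClusters(cl, sim$sets)
enr
#> EnrichmentTable: 49 tests over 7 clusters x 7 categories (per-cluster FDR)
#>   q < 0.05: 7 enriched
#>   ...
head(enrichmentResults(enr)[, c("cluster", "category", "nOverlap", "qValue")], 3)
#>   cluster  category nOverlap   qValue
#> 1       3 planted_2       19 1.20e-21
#> 2       5 planted_6       19 1.20e-21
#> 3       7 planted_1       20 4.21e-19
```

The simulated study plants six co-expression clusters (cluster 2 the
negation of cluster 1, mimicking a repressed program) plus a 3-gene
outlier group. After the 4–26-fold-change filter and log2 transform, the
6-dimensional Laplacian embedding separates the planted programs
(adjusted Rand 0.85 against truth), and each recovered cluster is
overrepresented for exactly its planted category at q far below 0.05.
The two tiny leading eigenvalues reflect the two most weakly connected
planted groups; the bandwidth is set to the data's log2 distance scale.
A semi-supervised run labels connectivity hubs first:

```r
g    <- heatWeights(knnGraph(em, 40), em)
hubs <- selectHubs(degreeConnectivity(g), 5)
se   <- schroedingerEigenmaps(em, 40, 2, labels = hubs, alpha = 100)
```

The same analyses run from the shell via `exec/geneigen`
(`simulate | filter | embed | cluster | sweep | enrich | pipeline`).

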