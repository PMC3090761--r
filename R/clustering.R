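# k-means (Lloyd) with silhouette-based restart selection, the
# squared-Euclidean silhouette coefficient, average-linkage hierarchical
# clustering, and the adjusted Rand index.

coordsOf <- function(points) {
    X <- if (is(points, "GeneEmbedding")) embeddingCoords(points)
         else as.matrix(points)
    if (is.null(rownames(X))) rownames(X) <- paste0("g", seq_len(nrow(X)))
    X
}

#' Lloyd's k-means with squared-Euclidean assignment
#'
#' Starts from k distinct points sampled uniformly without replacement,
#' then alternates nearest-centroid assignment (squared Euclidean
#' distance, ties to the lowest cluster index) and centroid means until
#' the assignment reaches a fixpoint or \code{maxIter}. A cluster emptied
#' during iteration is re-seeded at the point farthest from its assigned
#' centroid (deterministic). The objective (within-cluster sum of squared
#' distances) is recorded after every iteration and is non-increasing.
#' Silhouette coefficients are attached when k >= 2.
#'
#' @param points a \linkS4class{GeneEmbedding} or numeric matrix (rows =
#'   genes).
#' @param k number of clusters, at most the number of distinct points.
#' @param seed integer seed for centroid initialization.
#' @param maxIter iteration cap (default 100).
#' @return A \linkS4class{GeneClustering}.
#' @examples
#' cl <- lloydKMeans(cbind(c(0, 1, 10, 11)), k = 2, seed = 1)
#' clusterAssignment(cl); cl@objective
#' @export
lloydKMeans <- function(points, k, seed = 1L, maxIter = 100L) {
    X <- coordsOf(points)
    n <- nrow(X)
    if (n == 0L) stop("empty input")
    k <- assertCount(k, "k")
    maxIter <- assertCount(maxIter, "maxIter")
    distinct <- !duplicated(X)
    if (k > sum(distinct))
        stop(sprintf("k = %d exceeds the number of distinct points (%d)",
            k, sum(distinct)))
    init <- withSeed(seed, sample(which(distinct), k))
    C <- X[init, , drop = FALSE]
    assign <- integer(n)
    trace <- numeric(0)
    for (iter in seq_len(maxIter)) {
        D2 <- crossSquaredDistance(X, C)
        newAssign <- apply(D2, 1L, which.min)   # first minimum = lowest index
        assignedDist <- D2[cbind(seq_len(n), newAssign)]
        farOrder <- order(-assignedDist, seq_len(n))
        nextFar <- 1L
        for (j in seq_len(k)) {
            members <- which(newAssign == j)
            if (length(members)) {
                C[j, ] <- colMeans(X[members, , drop = FALSE])
            } else {
                # re-seed at the point farthest from its assigned centroid
                # (distinct points for multiple empty clusters)
                C[j, ] <- X[farOrder[nextFar], ]
                nextFar <- nextFar + 1L
            }
        }
        trace <- c(trace,
            sum(crossSquaredDistance(X, C)[cbind(seq_len(n), newAssign)]))
        if (identical(newAssign, assign)) { assign <- newAssign; break }
        assign <- newAssign
    }
    sil <- if (k >= 2L && length(unique(assign)) >= 2L)
        sqSilhouette(X, assign)
    else list(perPoint = rep(NA_real_, n), perCluster = NA_real_,
        overall = NA_real_)
    new("GeneClustering", geneIds = rownames(X),
        assignment = as.integer(assign), k = k, centroids = C,
        objective = trace[length(trace)], objectiveTrace = trace,
        perPointSil = sil$perPoint, perClusterSil = sil$perCluster,
        overallSil = sil$overall, seed = as.integer(seed),
        nRestarts = 1L, restartSil = sil$overall)
}

#' Silhouette coefficients with squared Euclidean distance
#'
#' For each point x, A(x) is the mean squared Euclidean distance to the
#' other members of its cluster and B(x) the minimum over other clusters
#' of the mean squared distance to that cluster's members; sil(x) =
#' (B - A) / max(A, B). Points in singleton clusters get silhouette 0.
#' Cluster and overall coefficients are plain means.
#'
#' @param points numeric matrix or \linkS4class{GeneEmbedding}.
#' @param assignment integer cluster index per point; at least two
#'   clusters must be non-empty.
#' @return List with \code{perPoint}, \code{perCluster} (named by cluster
#'   index) and \code{overall}.
#' @export
sqSilhouette <- function(points, assignment) {
    X <- coordsOf(points)
    n <- nrow(X)
    assignment <- as.integer(assignment)
    if (length(assignment) != n)
        stop("assignment length must match number of points")
    present <- sort(unique(assignment))
    if (length(present) < 2L)
        stop("silhouette undefined for a single cluster")
    D2 <- squaredDistanceMatrix(X)
    sizes <- tabulate(assignment, nbins = max(present))
    # mean distance from every point to every cluster, n x nClusters
    M <- vapply(present, function(j)
        rowSums(D2[, assignment == j, drop = FALSE]) / sizes[j],
        numeric(n))
    colIdx <- match(assignment, present)
    sil <- numeric(n)
    for (i in seq_len(n)) {
        sz <- sizes[assignment[i]]
        if (sz == 1L) { sil[i] <- 0; next }
        A <- M[i, colIdx[i]] * sz / (sz - 1L)   # exclude self
        B <- min(M[i, -colIdx[i]])
        sil[i] <- if (max(A, B) > 0) (B - A) / max(A, B) else 0
    }
    perCluster <- vapply(present, function(j) mean(sil[assignment == j]),
        numeric(1))
    list(perPoint = sil,
        perCluster = stats::setNames(perCluster, present),
        overall = mean(sil))
}

#' Best-of-restarts k-means selected by silhouette
#'
#' Runs [lloydKMeans()] with seeds \code{seed, seed + 1, ...,
#' seed + nRestarts - 1} and returns the run with the maximal overall
#' silhouette coefficient (not the minimal within-cluster sum of squares).
#' All restart silhouettes are kept in \code{restartSil} for stability
#' reporting.
#'
#' @inheritParams lloydKMeans
#' @param nRestarts number of restarts (default 100).
#' @return A \linkS4class{GeneClustering}; \code{slot seed} is the base
#'   seed, \code{restartSil} the logged silhouettes.
#' @export
bestKMeans <- function(points, k, nRestarts = 100L, seed = 1L,
                       maxIter = 100L) {
    nRestarts <- assertCount(nRestarts, "nRestarts")
    best <- NULL
    sils <- numeric(nRestarts)
    for (r in seq_len(nRestarts)) {
        cl <- lloydKMeans(points, k, seed = seed + r - 1L, maxIter = maxIter)
        sils[r] <- cl@overallSil
        if (is.null(best) ||
            (!is.na(cl@overallSil) &&
             (is.na(best@overallSil) || cl@overallSil > best@overallSil)))
            best <- cl
    }
    best@nRestarts <- nRestarts
    best@restartSil <- sils
    best
}

#' @rdname accessors
#' @export
setMethod("geneIds", "GeneClustering", function(x) x@geneIds)

#' @rdname accessors
#' @export
setMethod("clusterAssignment", "GeneClustering",
    function(x) stats::setNames(x@assignment, x@geneIds))

#' @rdname accessors
#' @export
setMethod("clusterCentroids", "GeneClustering", function(x) x@centroids)

#' @rdname accessors
#' @export
setMethod("overallSilhouette", "GeneClustering", function(x) x@overallSil)

setMethod("show", "GeneClustering", function(object) {
    cat(sprintf(
        "GeneClustering: %d genes in %d clusters (objective %.4g)\n",
        length(object@geneIds), object@k, object@objective))
    if (!is.na(object@overallSil))
        cat(sprintf("overall silhouette %.4f (%d restart%s)\n",
            object@overallSil, object@nRestarts,
            if (object@nRestarts == 1L) "" else "s"))
})

#' Per-cluster summary table
#'
#' @param x a \linkS4class{GeneClustering}.
#' @return data.frame with columns \code{cluster}, \code{size},
#'   \code{sil} (mean silhouette), the usual per-cluster report shape.
#' @export
clusterSummary <- function(x) {
    sizes <- tabulate(x@assignment, nbins = x@k)
    sil <- rep(NA_real_, x@k)
    nm <- as.integer(names(x@perClusterSil))
    if (length(nm)) sil[nm] <- unname(x@perClusterSil)
    data.frame(cluster = seq_len(x@k), size = sizes, sil = sil)
}

#' Average-linkage hierarchical clustering
#'
#' Agglomerative clustering with the Euclidean metric and unweighted
#' average linkage (UPGMA); merge heights are non-decreasing.
#'
#' @param points numeric matrix or \linkS4class{GeneEmbedding} with >= 2
#'   rows.
#' @return An object of class \code{hclust}.
#' @seealso [cutDendrogram()]
#' @export
averageLinkage <- function(points) {
    X <- coordsOf(points)
    if (nrow(X) < 2L) stop("need at least 2 points")
    stats::hclust(stats::dist(X, method = "euclidean"), method = "average")
}

#' Cut a dendrogram into flat clusters
#'
#' @param tree an \code{hclust} tree from [averageLinkage()].
#' @param k desired number of clusters, or
#' @param h height at which to cut.
#' @return Named integer vector of cluster memberships.
#' @export
cutDendrogram <- function(tree, k = NULL, h = NULL) {
    stats::cutree(tree, k = k, h = h)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement; 1 for identical partitions
#' (up to relabeling), about 0 for independent ones.
#'
#' @param a,b cluster assignments of equal length.
#' @return Numeric scalar in [-1, 1].
#' @export
adjustedRandIndex <- function(a, b) {
    if (length(a) != length(b))
        stop("assignments must have equal length")
    mclust::adjustedRandIndex(a, b)
}

#' Write a clustering as TSV
#'
#' @param x a \linkS4class{GeneClustering}.
#' @param path output path; columns gene_id, cluster, per_point_sil.
#' @return \code{path}, invisibly.
#' @export
writeClustering <- function(x, path) {
    utils::write.table(
        data.frame(gene_id = x@geneIds, cluster = x@assignment,
            per_point_sil = x@perPointSil, stringsAsFactors = FALSE),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
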