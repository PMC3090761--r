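#' @import methods
#' @importClassesFrom Matrix dgCMatrix
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
NULL

#' Gene expression matrix container
#'
#' Genes-by-samples expression values stored as a
#' \linkS4class{SummarizedExperiment} with a single \code{"exprs"} assay.
#' Rows are genes (unique identifiers), columns are ordered samples,
#' typically time points of a developmental series. The \code{logScale}
#' flag records whether values are on the log2 scale; on the linear scale
#' all values must be strictly positive so that per-gene fold changes
#' (max/min across the series) are defined.
#'
#' @slot logScale logical scalar; \code{TRUE} when values are log2-scale.
#' @seealso [ExpressionMatrix()], [readExpressionMatrix()],
#'   [foldChangeFilter()]
#' @export
setClass("ExpressionMatrix",
    contains = "SummarizedExperiment",
    slots = c(logScale = "logical"),
    prototype = prototype(logScale = FALSE)
)

setValidity("ExpressionMatrix", function(object) {
    v <- SummarizedExperiment::assay(object, "exprs")
    if (nrow(v) < 1L || ncol(v) < 1L)
        return("need at least one gene and one sample")
    ids <- rownames(v)
    if (is.null(ids) || anyNA(ids) || any(ids == ""))
        return("all genes must carry a non-empty identifier")
    if (anyDuplicated(ids))
        return(sprintf("duplicate gene identifiers: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (!all(is.finite(v)))
        return("expression values must all be finite")
    if (length(object@logScale) != 1L || is.na(object@logScale))
        return("logScale must be TRUE or FALSE")
    if (!object@logScale && any(v <= 0))
        return("linear-scale expression values must be strictly positive")
    TRUE
})

#' Named collection of gene sets
#'
#' Named list of gene identifier vectors, e.g. parsed from a GMT file,
#' used as the category universe in overrepresentation tests.
#'
#' @slot sets named list of character vectors, one per category; members
#'   are de-duplicated.
#' @slot descriptions named character vector of free-text descriptions,
#'   parallel to \code{sets}.
#' @seealso [readGeneSets()], [fisherEnrichment()]
#' @export
setClass("GeneSetCollection",
    slots = c(sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
    nm <- names(object@sets)
    if (length(object@sets) == 0L) return(TRUE)   # empty collection is valid
    if (is.null(nm) || anyNA(nm) || any(nm == ""))
        return("every gene set must be named")
    if (anyDuplicated(nm))
        return(sprintf("duplicate category names: %s",
            paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    if (any(lengths(object@sets) == 0L))
        return("every gene set must be non-empty")
    if (!all(vapply(object@sets, is.character, logical(1))))
        return("gene sets must be character vectors")
    if (!identical(sort(names(object@descriptions)), sort(nm)))
        return("descriptions must be named after the sets")
    TRUE
})

#' m-nearest-neighbor graph with heat-kernel weights
#'
#' Symmetric neighborhood graph over genes: nodes i and j are connected
#' when one is among the m nearest neighbors of the other (Euclidean
#' distance between expression profiles). Edge weights, once set by
#' [heatWeights()], follow the heat kernel
#' \eqn{W_{ij} = \exp(-\|x_i-x_j\|^2/\sigma)}. The per-node weighted
#' degree (row sums of W) doubles as a connectivity score for hub
#' detection.
#'
#' @slot geneIds character vector of node identifiers, in matrix row order.
#' @slot adjacency symmetric sparse 0/1 matrix with zero diagonal.
#' @slot weights symmetric sparse weight matrix; a 0x0 matrix until
#'   [heatWeights()] has been applied.
#' @slot m integer, neighbor count used to build the graph.
#' @slot sigma numeric heat-kernel bandwidth; \code{NA} until weights set.
#' @slot nComponents integer, cached number of connected components.
#' @seealso [knnGraph()], [heatWeights()], [graphLaplacian()]
#' @export
setClass("NeighborWeightGraph",
    slots = c(
        geneIds = "character",
        adjacency = "dgCMatrix",
        weights = "dgCMatrix",
        m = "integer",
        sigma = "numeric",
        nComponents = "integer"
    )
)

setValidity("NeighborWeightGraph", function(object) {
    n <- length(object@geneIds)
    A <- object@adjacency
    if (nrow(A) != n || ncol(A) != n)
        return("adjacency dimension must match number of genes")
    if (!Matrix::isSymmetric(A))
        return("adjacency must be symmetric")
    if (any(Matrix::diag(A) != 0))
        return("no self-edges allowed")
    if (hasWeights(object)) {
        W <- object@weights
        if (nrow(W) != n)
            return("weight matrix dimension must match number of genes")
        if (!Matrix::isSymmetric(W))
            return("weight matrix must be symmetric")
        if (any(W@x < 0))
            return("weights must be non-negative")
        if (any(Matrix::diag(W) != 0))
            return("weight matrix must have a zero diagonal")
    }
    TRUE
})

#' Graph Laplacian, optionally with a label potential
#'
#' Holds L = D - W for a weighted neighborhood graph together with its
#' symmetric normalization \eqn{D^{-1/2} L D^{-1/2}} and, when a label set
#' is supplied, the attractive clique potential V (Laplacian of the
#' complete unit-weight graph on the labeled nodes) and the Schroedinger
#' operator E = L + alpha V.
#'
#' @slot geneIds character node identifiers.
#' @slot L sparse combinatorial Laplacian.
#' @slot degree numeric weighted degrees (diagonal of D).
#' @slot V sparse potential matrix (all-zero when no labels).
#' @slot alpha non-negative potential strength.
#' @seealso [graphLaplacian()], [schroedingerEigenmaps()]
#' @export
setClass("LaplacianOperator",
    slots = c(
        geneIds = "character",
        L = "dgCMatrix",
        degree = "numeric",
        V = "dgCMatrix",
        alpha = "numeric"
    )
)

#' Low-dimensional gene embedding
#'
#' n x d coordinates from Laplacian Eigenmaps, Schroedinger Eigenmaps or
#' PCA, with the associated eigenvalues and the parameters used.
#'
#' @slot geneIds character identifiers, row order of \code{coords}.
#' @slot coords numeric n x d coordinate matrix.
#' @slot eigenvalues numeric; for spectral methods the d smallest
#'   non-trivial generalized eigenvalues (increasing), for PCA the leading
#'   covariance eigenvalues (decreasing).
#' @slot method one of \code{"laplacian"}, \code{"schroedinger"},
#'   \code{"pca"}, \code{"none"}.
#' @slot params list of parameters (m, d, sigma, alpha, labels, ...).
#' @export
setClass("GeneEmbedding",
    slots = c(
        geneIds = "character",
        coords = "matrix",
        eigenvalues = "numeric",
        method = "character",
        params = "list"
    )
)

setValidity("GeneEmbedding", function(object) {
    if (nrow(object@coords) != length(object@geneIds))
        return("coordinate rows must match gene identifiers")
    if (!object@method %in% c("laplacian", "schroedinger", "pca", "none"))
        return("unknown embedding method")
    TRUE
})

#' k-means clustering with silhouette scores
#'
#' Gene-to-cluster assignment from Lloyd's algorithm, with centroids, the
#' within-cluster sum of squared Euclidean distances (and its per-iteration
#' trace), and squared-Euclidean silhouette coefficients per point, per
#' cluster and overall.
#'
#' @slot geneIds character identifiers.
#' @slot assignment integer cluster index per gene, in 1..k.
#' @slot k integer cluster count.
#' @slot centroids k x dim numeric matrix of cluster means.
#' @slot objective within-cluster sum of squared distances at convergence.
#' @slot objectiveTrace objective after each Lloyd iteration.
#' @slot perPointSil,perClusterSil,overallSil silhouette coefficients
#'   (squared Euclidean distance).
#' @slot seed integer seed that produced this run.
#' @slot nRestarts number of restarts examined (1 for a single run).
#' @slot restartSil overall silhouettes logged across restarts.
#' @export
setClass("GeneClustering",
    slots = c(
        geneIds = "character",
        assignment = "integer",
        k = "integer",
        centroids = "matrix",
        objective = "numeric",
        objectiveTrace = "numeric",
        perPointSil = "numeric",
        perClusterSil = "numeric",
        overallSil = "numeric",
        seed = "integer",
        nRestarts = "integer",
        restartSil = "numeric"
    )
)

setValidity("GeneClustering", function(object) {
    n <- length(object@geneIds)
    if (length(object@assignment) != n)
        return("assignment length must match gene identifiers")
    if (any(object@assignment < 1L | object@assignment > object@k))
        return("cluster indices must lie in 1..k")
    if (length(object@objective) == 1L && object@objective < 0)
        return("objective must be non-negative")
    sil <- object@perPointSil
    if (length(sil) && any(abs(sil[!is.na(sil)]) > 1 + 1e-12))
        return("silhouettes must lie in [-1, 1]")
    TRUE
})

#' Neighborhood-size / dimension sweep result
#'
#' Grid of overall silhouette coefficients over combinations of the
#' neighbor count m and target dimension d, with the silhouette-maximizing
#' cell (ties broken toward smaller d, then smaller m).
#'
#' @slot grid data.frame with columns m, d, overallSil, nComponents,
#'   status.
#' @slot best list with elements m, d, overallSil.
#' @seealso [parameterSweep()]
#' @export
setClass("SweepResult",
    slots = c(grid = "data.frame", best = "list"))

#' Gene-set overrepresentation results
#'
#' Per (cluster, category) contingency counts with one-sided Fisher
#' (hypergeometric upper-tail) p-values and Benjamini-Hochberg q-values,
#' plus enriched-category counts per FDR threshold and the cluster-by-
#' category q-value matrix (text twin of a clustered image map).
#'
#' @slot table data.frame with columns cluster, category, nUniverse,
#'   nCategory, nCluster, nOverlap, pValue, qValue, overlapGenes.
#' @slot counts data.frame of enriched-category counts per cluster and
#'   threshold.
#' @slot sigMatrix numeric clusters x categories matrix of q-values.
#' @slot fdrMode \code{"per-cluster"} or \code{"global"} adjustment family.
#' @slot thresholds numeric FDR thresholds used for counting.
#' @export
setClass("EnrichmentTable",
    slots = c(
        table = "data.frame",
        counts = "data.frame",
        sigMatrix = "matrix",
        fdrMode = "character",
        thresholds = "numeric"
    )
)
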