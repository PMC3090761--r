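#' Build the m-nearest-neighbor graph over genes
#'
#' Connects genes i and j when i is among the m nearest neighbors of j or
#' vice versa (OR symmetrization), with distance measured by the Euclidean
#' metric between expression profiles. Neighbor ties are broken by
#' (distance, gene index) so the graph is deterministic across platforms.
#' The result carries edges only; call [heatWeights()] to set weights.
#'
#' @param x an \linkS4class{ExpressionMatrix} (or numeric matrix, rows =
#'   genes).
#' @param m neighbor count, \code{1 <= m <= n - 1}.
#' @return A \linkS4class{NeighborWeightGraph} with weights unset.
#' @examples
#' em <- ExpressionMatrix(cbind(x = c(0, 1, 3, 7)),
#'     geneIds = letters[1:4], logScale = TRUE)
#' g <- knnGraph(em, m = 1)
#' nComponents(g)
#' @export
knnGraph <- function(x, m) {
    X <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
    n <- nrow(X)
    if (n < 2L) stop("need at least 2 genes to build a graph")
    m <- assertCount(m, "m")
    if (m > n - 1L)
        stop(sprintf("m = %d out of range; must be <= n - 1 = %d", m, n - 1L))
    ids <- rownames(X)
    if (is.null(ids)) ids <- paste0("g", seq_len(n))
    D2 <- squaredDistanceMatrix(X)
    ii <- integer(0); jj <- integer(0)
    for (i in seq_len(n)) {
        ord <- order(D2[i, ], seq_len(n))
        ord <- ord[ord != i][seq_len(m)]
        ii <- c(ii, rep.int(i, m)); jj <- c(jj, ord)
    }
    A <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
    A <- methods::as(A + Matrix::t(A), "dgCMatrix")   # OR symmetrization
    A@x[] <- 1
    Matrix::diag(A) <- 0
    A <- methods::as(Matrix::drop0(A), "dgCMatrix")
    comps <- igraph::components(igraph::graph_from_adjacency_matrix(
        A, mode = "undirected"))$no
    new("NeighborWeightGraph", geneIds = ids,
        adjacency = methods::as(A, "dgCMatrix"),
        weights = Matrix::sparseMatrix(i = integer(0), j = integer(0),
            x = numeric(0), dims = c(0L, 0L)),
        m = m, sigma = NA_real_, nComponents = as.integer(comps))
}

#' Assign heat-kernel weights to a neighborhood graph
#'
#' Sets \eqn{W_{ij} = \exp(-\|x_i - x_j\|^2 / \sigma)} on every edge of the
#' graph (zero elsewhere) and recomputes node degrees. \code{x} must be the
#' matrix the edges were built from.
#'
#' @param graph a \linkS4class{NeighborWeightGraph} from [knnGraph()].
#' @param x the \linkS4class{ExpressionMatrix} (or matrix) used to build
#'   the graph.
#' @param sigma positive heat-kernel bandwidth (default 1/8).
#' @return The graph with weights set.
#' @export
heatWeights <- function(graph, x, sigma = 1 / 8) {
    X <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
    sigma <- assertPositiveScalar(sigma, "sigma")
    n <- length(graph@geneIds)
    if (nrow(X) != n)
        stop("graph and matrix disagree on the number of genes")
    A <- methods::as(graph@adjacency, "TsparseMatrix")
    d2 <- rowSums((X[A@i + 1L, , drop = FALSE] -
                   X[A@j + 1L, , drop = FALSE])^2)
    W <- Matrix::sparseMatrix(i = A@i + 1L, j = A@j + 1L,
        x = exp(-d2 / sigma), dims = c(n, n))
    # exp() of identical squared distances is symmetric by construction;
    # enforce exactly to guard against summation-order effects
    W <- (W + Matrix::t(W)) / 2
    graph@weights <- methods::as(W, "dgCMatrix")
    graph@sigma <- sigma
    methods::validObject(graph)
    graph
}

#' @rdname accessors
#' @export
setMethod("geneIds", "NeighborWeightGraph", function(x) x@geneIds)

#' @rdname accessors
#' @export
setMethod("hasWeights", "NeighborWeightGraph",
    function(x) nrow(x@weights) > 0L)

#' @rdname accessors
#' @export
setMethod("weightMatrix", "NeighborWeightGraph", function(x) {
    if (!hasWeights(x)) stop("weights not set; call heatWeights() first")
    x@weights
})

#' @rdname accessors
#' @export
setMethod("nodeDegrees", "NeighborWeightGraph", function(x) {
    stats::setNames(Matrix::rowSums(weightMatrix(x)), x@geneIds)
})

#' @rdname accessors
#' @export
setMethod("nComponents", "NeighborWeightGraph", function(x) x@nComponents)

setMethod("show", "NeighborWeightGraph", function(object) {
    nE <- Matrix::nnzero(object@adjacency) / 2
    cat(sprintf(
        "NeighborWeightGraph: %d nodes, %d edges (m = %d, %d component%s)\n",
        length(object@geneIds), nE, object@m, object@nComponents,
        if (object@nComponents == 1L) "" else "s"))
    cat(if (hasWeights(object))
        sprintf("heat-kernel weights set (sigma = %g)\n", object@sigma)
    else "weights unset\n")
})

# Membership vector of connected components (internal).
componentMembership <- function(graph) {
    igraph::components(igraph::graph_from_adjacency_matrix(
        graph@adjacency, mode = "undirected"))$membership
}

#' Graph Laplacian with optional label potential
#'
#' Computes L = D - W where D is the diagonal degree matrix
#' \eqn{D_{ii} = \sum_j W_{ij}}. When \code{labels} are given, adds the
#' attractive clique potential V — the Laplacian of the complete
#' unit-weight graph on the labeled nodes, so that
#' \eqn{y^\top V y = \sum_{i<j \in S}(y_i - y_j)^2} — scaled by
#' \code{alpha}, yielding the Schroedinger operator E = L + alpha V.
#'
#' @param graph weighted \linkS4class{NeighborWeightGraph}.
#' @param labels optional character vector of labeled gene ids (>= 2 when
#'   given).
#' @param alpha non-negative potential strength (ignored without labels).
#' @return A \linkS4class{LaplacianOperator}.
#' @export
graphLaplacian <- function(graph, labels = NULL, alpha = 0) {
    W <- weightMatrix(graph)
    deg <- Matrix::rowSums(W)
    if (any(deg == 0)) {
        bad <- graph@geneIds[deg == 0]
        stop(sprintf(
            "isolated node(s) with zero degree (%s); increase m",
            paste(utils::head(bad, 5), collapse = ", ")))
    }
    n <- length(deg)
    L <- Matrix::Diagonal(n, deg) - W
    if (is.null(labels)) {
        V <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
            x = numeric(0), dims = c(n, n))
        alpha <- 0
    } else {
        if (alpha < 0) stop("'alpha' must be non-negative")
        idx <- match(labels, graph@geneIds)
        if (anyNA(idx))
            stop(sprintf("labels not found in graph: %s",
                paste(labels[is.na(idx)], collapse = ", ")))
        if (length(idx) < 2L) stop("need at least 2 labeled genes")
        s <- length(idx)
        V <- Matrix::sparseMatrix(
            i = rep(idx, each = s), j = rep(idx, times = s),
            x = rep(-1, s * s), dims = c(n, n))
        Matrix::diag(V)[idx] <- s - 1
        V <- Matrix::drop0(V)
    }
    new("LaplacianOperator", geneIds = graph@geneIds,
        L = methods::as(methods::as(L, "generalMatrix"), "dgCMatrix"),
        degree = as.numeric(deg),
        V = methods::as(methods::as(V, "generalMatrix"), "dgCMatrix"),
        alpha = as.numeric(alpha))
}

#' Combined operator E = L + alpha V of a LaplacianOperator
#' @param x a \linkS4class{LaplacianOperator}
#' @return Sparse symmetric matrix E.
#' @export
schroedingerOperator <- function(x) x@L + x@alpha * x@V

#' Symmetrically normalized operator D^(-1/2) (L + alpha V) D^(-1/2)
#' @param x a \linkS4class{LaplacianOperator}
#' @return Sparse symmetric matrix.
#' @export
normalizedOperator <- function(x) {
    s <- 1 / sqrt(x@degree)
    S <- Matrix::Diagonal(length(s), s)
    S %*% schroedingerOperator(x) %*% S
}

setMethod("show", "LaplacianOperator", function(object) {
    cat(sprintf("LaplacianOperator: %d nodes", length(object@geneIds)))
    if (object@alpha > 0)
        cat(sprintf(", Schroedinger potential on %d labels (alpha = %g)",
            sum(Matrix::diag(object@V) > 0), object@alpha))
    cat("\n")
})

#' Degree-based gene connectivity scores
#'
#' Scores each gene by its weighted degree in the heat-kernel graph — the
#' diagonal of the degree matrix D, a direct measure of connectivity in
#' the network. Sorted descending; ties broken by gene id.
#'
#' @param graph weighted \linkS4class{NeighborWeightGraph}.
#' @return data.frame with columns \code{gene_id}, \code{score},
#'   \code{rank} (descending score).
#' @seealso [selectHubs()], [correlationConnectivity()]
#' @export
degreeConnectivity <- function(graph) {
    sc <- nodeDegrees(graph)
    ord <- order(-sc, names(sc))
    data.frame(gene_id = names(sc)[ord], score = unname(sc[ord]),
        rank = seq_along(sc), stringsAsFactors = FALSE)
}

#' Correlation-based gene connectivity scores
#'
#' Weighted co-expression connectivity: the soft-power adjacency
#' \eqn{a_{ij} = |cor(x_i, x_j)|^\beta} (unsigned Pearson correlation,
#' \eqn{i \ne j}) summed per gene. This is the connectivity statistic of
#' weighted correlation network analysis, without soft-threshold
#' selection or module detection.
#'
#' @param x an \linkS4class{ExpressionMatrix} (or matrix) with >= 3 genes;
#'   every gene needs nonzero variance across samples.
#' @param beta positive soft-thresholding power (default 6, the common
#'   convention for unsigned networks).
#' @return data.frame with columns \code{gene_id}, \code{score},
#'   \code{rank}, sorted descending with ties broken by gene id.
#' @export
correlationConnectivity <- function(x, beta = 6) {
    X <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
    beta <- assertPositiveScalar(beta, "beta")
    if (nrow(X) < 3L) stop("need at least 3 genes")
    ids <- rownames(X)
    if (is.null(ids)) ids <- paste0("g", seq_len(nrow(X)))
    v <- apply(X, 1L, stats::var)
    if (any(v == 0))
        stop(sprintf("zero-variance gene(s): %s",
            paste(ids[v == 0], collapse = ", ")))
    A <- abs(stats::cor(t(X)))^beta
    diag(A) <- 0
    sc <- stats::setNames(rowSums(A), ids)
    ord <- order(-sc, names(sc))
    data.frame(gene_id = names(sc)[ord], score = unname(sc[ord]),
        rank = seq_along(sc), stringsAsFactors = FALSE)
}

#' Thresholded correlation network edge list
#'
#' Edges of the soft-power correlation network with adjacency at or above
#' a threshold, for hub counting by connection number.
#'
#' @inheritParams correlationConnectivity
#' @param tau threshold in (0, 1]; edges with \eqn{a_{ij} \ge \tau} kept.
#' @return data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{weight}.
#' @export
thresholdNetwork <- function(x, beta = 6, tau = 0.5) {
    X <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
    ids <- rownames(X)
    if (is.null(ids)) ids <- paste0("g", seq_len(nrow(X)))
    A <- abs(stats::cor(t(X)))^beta
    diag(A) <- 0
    keep <- which(upper.tri(A) & A >= tau, arr.ind = TRUE)
    data.frame(gene_a = ids[keep[, 1L]], gene_b = ids[keep[, 2L]],
        weight = A[keep], stringsAsFactors = FALSE)
}

#' Select top-connectivity hub genes
#'
#' Picks the \code{count} highest-scoring genes from a connectivity table,
#' with deterministic ties broken by gene id. These hubs are the natural
#' label set for [schroedingerEigenmaps()].
#'
#' @param scores connectivity table from [degreeConnectivity()] or
#'   [correlationConnectivity()].
#' @param count number of hubs, \code{1 <= count <= n}. Common choices are
#'   7 (correlation-derived labels) and 5 (degree-derived labels).
#' @return Character vector of hub gene ids.
#' @export
selectHubs <- function(scores, count) {
    count <- assertCount(count, "count")
    if (count > nrow(scores))
        stop(sprintf("count = %d exceeds number of genes (%d)",
            count, nrow(scores)))
    ord <- order(-scores$score, scores$gene_id)
    scores$gene_id[ord][seq_len(count)]
}
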