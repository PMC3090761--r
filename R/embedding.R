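# Spectral embeddings: Laplacian Eigenmaps, Schroedinger Eigenmaps, PCA.
#
# Both spectral methods solve the generalized problem (L + alpha V) x =
# lambda D x through the change of variables z = D^(1/2) y, which turns it
# into an ordinary symmetric eigenproblem on D^(-1/2) (L + alpha V)
# D^(-1/2). Eigenvectors z are orthonormal, so y = D^(-1/2) z satisfies
# y^T D y = I automatically.

# Smallest nTotal eigenpairs of a sparse symmetric PSD matrix. Dense path
# for moderate n; ARPACK (Lanczos, smallest-algebraic) above, with a dense
# fallback if ARPACK fails to converge.
smallestEigenpairs <- function(M, nTotal, denseLimit = 800L) {
    n <- nrow(M)
    nTotal <- min(nTotal, n)
    if (n <= denseLimit) {
        e <- eigen(as.matrix(Matrix::forceSymmetric(M)), symmetric = TRUE)
        idx <- seq.int(n, n - nTotal + 1L)
        return(list(values = e$values[idx],
            vectors = e$vectors[, idx, drop = FALSE]))
    }
    res <- tryCatch({
        a <- igraph::arpack(
            function(v, extra = NULL) as.numeric(M %*% v),
            sym = TRUE,
            options = list(n = n, nev = nTotal,
                ncv = min(n, max(4L * nTotal + 1L, 40L)),
                which = "SA", maxiter = 10000L))
        vec <- a$vectors
        if (is.null(dim(vec))) vec <- matrix(vec, ncol = 1L)
        ord <- order(a$values)
        list(values = a$values[ord], vectors = vec[, ord, drop = FALSE])
    }, error = function(e) NULL)
    if (is.null(res)) {
        e <- eigen(as.matrix(Matrix::forceSymmetric(M)), symmetric = TRUE)
        idx <- seq.int(n, n - nTotal + 1L)
        res <- list(values = e$values[idx],
            vectors = e$vectors[, idx, drop = FALSE])
    }
    res
}

# Shared spectral-embedding engine over a LaplacianOperator.
spectralEmbed <- function(op, d, method, params) {
    n <- length(op@geneIds)
    if (d < 1L || d > n - 1L)
        stop(sprintf("d = %d out of range; spectral methods need 1 <= d <= n - 1",
            d))
    Msym <- normalizedOperator(op)
    # The null space of L + alpha V on a connected graph is exactly the
    # constant vector (the clique potential also annihilates constants),
    # so precisely one trivial mode is dropped — counting is robust where
    # a magnitude threshold would not be, e.g. under a strong potential
    # that stretches the spectrum by many orders of magnitude.
    pairs <- smallestEigenpairs(Msym, d + 1L)
    keep <- seq.int(2L, d + 1L)
    lambda <- pairs$values[keep]
    Z <- pairs$vectors[, keep, drop = FALSE]
    Y <- Z / sqrt(op@degree)            # y = D^(-1/2) z
    Y <- fixColumnSigns(Y)
    rownames(Y) <- op@geneIds
    colnames(Y) <- paste0("dim", seq_len(d))
    new("GeneEmbedding", geneIds = op@geneIds, coords = Y,
        eigenvalues = lambda, method = method, params = params)
}

# Restrict an ExpressionMatrix to the largest connected component of its
# m-NN graph; internal helper for the largestComponent escape hatch.
restrictToLargestComponent <- function(x, graph) {
    memb <- componentMembership(graph)
    keepComp <- which.max(tabulate(memb))
    keep <- memb == keepComp
    dropped <- geneIds(graph)[!keep]
    warning(sprintf(
        "graph has %d components; embedding the largest (%d genes), dropping %d",
        nComponents(graph), sum(keep), length(dropped)))
    list(matrix = ExpressionMatrix(exprValues(x)[keep, , drop = FALSE],
        logScale = isLogScale(x)), dropped = dropped)
}

#' Laplacian Eigenmaps embedding
#'
#' Nonlinear dimension reduction: builds the m-nearest-neighbor graph with
#' heat-kernel weights \eqn{W_{ij} = \exp(-\|x_i-x_j\|^2/\sigma)}, forms
#' L = D - W, and maps genes to the eigenvectors of the d smallest
#' non-trivial generalized eigenvalues of \eqn{Lx = \lambda Dx}. The
#' constant eigenvector (eigenvalue 0) is excluded; the returned
#' coordinates satisfy \eqn{y^\top D y = I}. Requires a connected graph.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param m neighbor count.
#' @param d target dimension, \code{1 <= d <= n - 1}.
#' @param sigma heat-kernel bandwidth (default 1/8).
#' @param largestComponent if \code{TRUE}, a disconnected graph is not an
#'   error: the largest component is embedded and dropped genes are
#'   recorded in \code{params$dropped}.
#' @return A \linkS4class{GeneEmbedding} with \code{method = "laplacian"}.
#' @examples
#' set.seed(1)
#' em <- ExpressionMatrix(matrix(rnorm(160), 20, 8),
#'     geneIds = sprintf("g%02d", 1:20), logScale = TRUE)
#' emb <- laplacianEigenmaps(em, m = 4, d = 2)
#' head(embeddingCoords(emb))
#' @export
laplacianEigenmaps <- function(x, m, d, sigma = 1 / 8,
                               largestComponent = FALSE) {
    d <- assertCount(d, "d")
    g <- knnGraph(x, m)
    dropped <- character(0)
    if (nComponents(g) > 1L) {
        if (!largestComponent)
            stop(sprintf(
                "graph with m = %d has %d connected components; increase m (or set largestComponent = TRUE)",
                m, nComponents(g)))
        r <- restrictToLargestComponent(x, g)
        x <- r$matrix; dropped <- r$dropped
        g <- knnGraph(x, m)
    }
    g <- heatWeights(g, x, sigma)
    op <- graphLaplacian(g)
    spectralEmbed(op, d, "laplacian",
        list(m = m, d = d, sigma = sigma, dropped = dropped))
}

#' Schroedinger Eigenmaps embedding with labeled genes
#'
#' Semi-supervised variant of [laplacianEigenmaps()]: the Laplacian L is
#' replaced by the Schroedinger operator E = L + alpha V, where V is an
#' attractive clique potential on the labeled genes
#' (\eqn{y^\top V y = \sum_{i<j \in S} (y_i - y_j)^2}). Increasing
#' \code{alpha} pulls the labeled genes together in the embedding;
#' \code{alpha = 0} reproduces Laplacian Eigenmaps exactly.
#'
#' @inheritParams laplacianEigenmaps
#' @param labels character vector of >= 2 labeled gene ids, a subset of
#'   \code{geneIds(x)}; typically connectivity hubs from [selectHubs()].
#' @param alpha non-negative potential strength (default 1).
#' @return A \linkS4class{GeneEmbedding} with \code{method =
#'   "schroedinger"}.
#' @export
schroedingerEigenmaps <- function(x, m, d, sigma = 1 / 8, labels,
                                  alpha = 1, largestComponent = FALSE) {
    d <- assertCount(d, "d")
    if (alpha < 0) stop("'alpha' must be non-negative")
    labels <- unique(as.character(labels))
    missing <- setdiff(labels, geneIds(x))
    if (length(missing))
        stop(sprintf("labels not present in the matrix: %s",
            paste(missing, collapse = ", ")))
    if (length(labels) < 2L) stop("need at least 2 labeled genes")
    g <- knnGraph(x, m)
    dropped <- character(0)
    if (nComponents(g) > 1L) {
        if (!largestComponent)
            stop(sprintf(
                "graph with m = %d has %d connected components; increase m (or set largestComponent = TRUE)",
                m, nComponents(g)))
        r <- restrictToLargestComponent(x, g)
        x <- r$matrix; dropped <- r$dropped
        labels <- intersect(labels, geneIds(x))
        if (length(labels) < 2L)
            stop("fewer than 2 labeled genes remain in the largest component")
        g <- knnGraph(x, m)
    }
    g <- heatWeights(g, x, sigma)
    op <- graphLaplacian(g, labels = labels, alpha = alpha)
    spectralEmbed(op, d, "schroedinger",
        list(m = m, d = d, sigma = sigma, alpha = alpha, labels = labels,
            dropped = dropped))
}

#' PCA embedding (linear baseline)
#'
#' Mean-centers the gene vectors and projects them onto the leading
#' eigenvectors of the sample covariance matrix. Either a fixed dimension
#' \code{d} or a variance fraction may be given; with
#' \code{varianceFraction}, d is the smallest count of components whose
#' cumulative eigenvalue share reaches the fraction (0.85 is a common
#' choice for this kind of data).
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param d number of components (\code{<= D}); ignored when
#'   \code{varianceFraction} is given.
#' @param varianceFraction fraction of variance to retain, in (0, 1].
#' @return A \linkS4class{GeneEmbedding} with \code{method = "pca"};
#'   \code{params$varianceShares} holds the per-component shares.
#' @export
pcaEmbed <- function(x, d = NULL, varianceFraction = NULL) {
    X <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
    n <- nrow(X)
    if (n < 2L) stop("need at least 2 genes")
    ids <- rownames(X)
    if (is.null(ids)) ids <- paste0("g", seq_len(n))
    Xc <- sweep(X, 2L, colMeans(X))
    C <- crossprod(Xc) / (n - 1L)
    e <- eigen(C, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    total <- sum(ev)
    if (total <= 0) stop("zero total variance; PCA undefined")
    shares <- ev / total
    if (!is.null(varianceFraction)) {
        if (varianceFraction <= 0 || varianceFraction > 1)
            stop("'varianceFraction' must be in (0, 1]")
        d <- which(cumsum(shares) >= varianceFraction - 1e-12)[1L]
    } else if (is.null(d)) {
        stop("give either 'd' or 'varianceFraction'")
    }
    d <- assertCount(d, "d")
    if (d > ncol(X))
        stop(sprintf("d = %d exceeds the ambient dimension D = %d",
            d, ncol(X)))
    Y <- Xc %*% e$vectors[, seq_len(d), drop = FALSE]
    Y <- fixColumnSigns(Y)
    rownames(Y) <- ids
    colnames(Y) <- paste0("PC", seq_len(d))
    new("GeneEmbedding", geneIds = ids, coords = Y,
        eigenvalues = ev[seq_len(d)], method = "pca",
        params = list(d = d, varianceFraction = varianceFraction,
            varianceShares = shares))
}

#' Identity (no-reduction) embedding
#'
#' Wraps the raw expression vectors as a \linkS4class{GeneEmbedding} so
#' the clustering stage can run on unreduced data (the plain k-means arm).
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @return A \linkS4class{GeneEmbedding} with \code{method = "none"}.
#' @export
identityEmbed <- function(x) {
    X <- exprValues(x)
    new("GeneEmbedding", geneIds = rownames(X), coords = X,
        eigenvalues = numeric(0), method = "none", params = list())
}

#' @rdname accessors
#' @export
setMethod("geneIds", "GeneEmbedding", function(x) x@geneIds)

#' @rdname accessors
#' @export
setMethod("embeddingCoords", "GeneEmbedding", function(x) x@coords)

#' @rdname accessors
#' @export
setMethod("eigenValues", "GeneEmbedding", function(x) x@eigenvalues)

setMethod("show", "GeneEmbedding", function(object) {
    cat(sprintf("GeneEmbedding (%s): %d genes x %d dimensions\n",
        object@method, nrow(object@coords), ncol(object@coords)))
    if (length(object@eigenvalues))
        cat("eigenvalues:",
            paste(signif(object@eigenvalues, 5), collapse = ", "), "\n")
})

#' Write embedding coordinates and metadata
#'
#' @param x a \linkS4class{GeneEmbedding}.
#' @param path output TSV path (gene_id then coordinate columns); a
#'   companion \code{<path>.meta.json} records method, parameters and
#'   eigenvalues.
#' @return \code{path}, invisibly.
#' @export
writeEmbedding <- function(x, path) {
    df <- data.frame(gene_id = x@geneIds, x@coords, check.names = FALSE,
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    meta <- c(list(method = x@method, eigenvalues = x@eigenvalues),
        x@params[setdiff(names(x@params), "varianceShares")])
    jsonlite::write_json(meta, paste0(path, ".meta.json"),
        auto_unbox = TRUE, digits = NA, null = "null")
    invisible(path)
}
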