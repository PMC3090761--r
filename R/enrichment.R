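# Gene-set overrepresentation: one-sided Fisher (hypergeometric
# upper-tail) p-values per (cluster, category), Benjamini-Hochberg FDR.

#' One-sided Fisher overrepresentation test for one gene cluster
#'
#' For each category, counts the overlap with the cluster and computes the
#' upper-tail hypergeometric probability P(X >= overlap) of seeing at
#' least that overlap when drawing \code{|cluster|} genes from the
#' universe. Category members are intersected with the universe first;
#' categories smaller than \code{minCategorySize} after intersection are
#' skipped.
#'
#' @param clusterGenes character vector of gene ids (must be a subset of
#'   \code{universe}).
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param universe character vector of all tested gene ids.
#' @param minCategorySize smallest category kept after universe
#'   intersection (default 2).
#' @return data.frame with columns category, nUniverse, nCategory,
#'   nCluster, nOverlap, pValue, overlapGenes (comma-joined).
#' @examples
#' sets <- GeneSetCollection(list(A = c("g1", "g2", "g3")))
#' fisherEnrichment(c("g1", "g2"), sets, paste0("g", 1:20))
#' @export
fisherEnrichment <- function(clusterGenes, sets, universe,
                             minCategorySize = 2L) {
    universe <- unique(as.character(universe))
    if (!length(universe)) stop("empty universe")
    clusterGenes <- unique(as.character(clusterGenes))
    outside <- setdiff(clusterGenes, universe)
    if (length(outside))
        stop(sprintf("cluster genes outside the universe: %s",
            paste(utils::head(outside, 10), collapse = ", ")))
    N <- length(universe)
    nClu <- length(clusterGenes)
    rows <- lapply(names(geneSets(sets)), function(nm) {
        members <- intersect(geneSets(sets)[[nm]], universe)
        if (length(members) < minCategorySize) return(NULL)
        ov <- intersect(clusterGenes, members)
        K <- length(members)
        p <- stats::phyper(length(ov) - 1L, K, N - K, nClu,
            lower.tail = FALSE)
        data.frame(category = nm, nUniverse = N, nCategory = K,
            nCluster = nClu, nOverlap = length(ov), pValue = p,
            overlapGenes = paste(sort(ov), collapse = ","),
            stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(category = character(0), nUniverse = integer(0),
            nCategory = integer(0), nCluster = integer(0),
            nOverlap = integer(0), pValue = numeric(0),
            overlapGenes = character(0), stringsAsFactors = FALSE)
    out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment; q-values are monotone in the
#' p-value ranks and invariant to input order.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values.
#' @export
fdrAdjust <- function(p) {
    if (!length(p)) stop("empty p-value vector")
    if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Overrepresentation analysis of every cluster
#'
#' Tests every (cluster, category) pair with [fisherEnrichment()] and
#' adjusts p-values with Benjamini-Hochberg, either within each cluster's
#' family of categories (default) or pooling all cluster x category tests
#' (\code{fdrMode = "global"}). Reports enriched-category counts at each
#' threshold and the clusters x categories q-value matrix (the text twin
#' of a clustered image map).
#'
#' @param clustering a \linkS4class{GeneClustering}.
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param universe gene universe; by default the clustering's genes
#'   intersected with the union of set members.
#' @param thresholds FDR thresholds for counting (default 0.05, 0.10,
#'   0.15, 0.20).
#' @param fdrMode \code{"per-cluster"} or \code{"global"}.
#' @param minCategorySize passed to [fisherEnrichment()].
#' @return An \linkS4class{EnrichmentTable}; rows sorted by q then p.
#' @export
enrichAllClusters <- function(clustering, sets, universe = NULL,
                              thresholds = c(0.05, 0.10, 0.15, 0.20),
                              fdrMode = c("per-cluster", "global"),
                              minCategorySize = 2L) {
    fdrMode <- match.arg(fdrMode)
    assign <- clusterAssignment(clustering)
    if (is.null(universe))
        universe <- intersect(names(assign),
            unique(unlist(geneSets(sets), use.names = FALSE)))
    universe <- unique(as.character(universe))
    if (!length(universe))
        stop("empty universe: no clustered gene appears in any set")
    tabs <- lapply(sort(unique(assign)), function(cl) {
        genes <- intersect(names(assign)[assign == cl], universe)
        if (!length(genes)) return(NULL)
        t <- fisherEnrichment(genes, sets, universe, minCategorySize)
        if (!nrow(t)) return(NULL)
        cbind(cluster = cl, t)
    })
    tab <- do.call(rbind, tabs)
    if (is.null(tab) || !nrow(tab))
        stop("no testable (cluster, category) pairs")
    if (fdrMode == "global") {
        tab$qValue <- fdrAdjust(tab$pValue)
    } else {
        tab$qValue <- NA_real_
        for (cl in unique(tab$cluster)) {
            i <- tab$cluster == cl
            tab$qValue[i] <- fdrAdjust(tab$pValue[i])
        }
    }
    tab <- tab[order(tab$qValue, tab$pValue, tab$cluster, tab$category), ]
    rownames(tab) <- NULL
    clusters <- sort(unique(tab$cluster))
    cats <- sort(unique(tab$category))
    sig <- matrix(NA_real_, length(clusters), length(cats),
        dimnames = list(paste0("cluster", clusters), cats))
    sig[cbind(match(tab$cluster, clusters), match(tab$category, cats))] <-
        tab$qValue
    counts <- do.call(rbind, lapply(thresholds, function(th) {
        perCluster <- vapply(clusters, function(cl)
            sum(tab$qValue[tab$cluster == cl] < th), integer(1))
        data.frame(threshold = th, cluster = clusters,
            nEnriched = perCluster)
    }))
    new("EnrichmentTable", table = tab, counts = counts, sigMatrix = sig,
        fdrMode = fdrMode, thresholds = as.numeric(thresholds))
}

#' @rdname accessors
#' @export
setMethod("enrichmentResults", "EnrichmentTable", function(x) x@table)

setMethod("show", "EnrichmentTable", function(object) {
    cat(sprintf(
        "EnrichmentTable: %d tests over %d clusters x %d categories (%s FDR)\n",
        nrow(object@table), length(unique(object@table$cluster)),
        length(unique(object@table$category)), object@fdrMode))
    for (th in object@thresholds)
        cat(sprintf("  q < %.2f: %d enriched\n", th,
            sum(object@table$qValue < th)))
})

#' Total enriched-category count at a threshold
#'
#' @param x an \linkS4class{EnrichmentTable}.
#' @param threshold FDR threshold.
#' @return Integer count of (cluster, category) pairs with q below the
#'   threshold, summed over all clusters.
#' @export
enrichedCount <- function(x, threshold = 0.05) {
    sum(x@table$qValue < threshold)
}

#' Write enrichment results
#'
#' @param x an \linkS4class{EnrichmentTable}.
#' @param path output TSV path for the test table; the q-value
#'   significance matrix goes to \code{<path>.matrix.tsv}.
#' @return \code{path}, invisibly.
#' @export
writeEnrichment <- function(x, path) {
    utils::write.table(x@table, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    sig <- data.frame(cluster = rownames(x@sigMatrix), x@sigMatrix,
        check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(sig, paste0(path, ".matrix.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
    invisible(path)
}
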