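#' Sweep neighborhood size and target dimension
#'
#' For every (m, d) cell: embed with Laplacian Eigenmaps, cluster with
#' [bestKMeans()], and record the overall silhouette. Cells whose m-NN
#' graph is disconnected are skipped with a reason. The best cell is the
#' silhouette argmax, ties broken toward smaller d then smaller m
#' (parsimony). The eigendecomposition is shared across d for a given m,
#' since the d-dimensional spectral coordinates are nested.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param mGrid neighbor counts; default \code{c(5:10, 12, 15, 20, 25, 50,
#'   100)}.
#' @param dGrid target dimensions; default \code{c(1:10, 12, 16)}.
#' @param sigma heat-kernel bandwidth (default 1/8).
#' @param k cluster count (default 24).
#' @param nRestarts k-means restarts per cell (default 100).
#' @param seed base seed shared by every cell.
#' @return A \linkS4class{SweepResult}.
#' @export
parameterSweep <- function(x, mGrid = c(5:10, 12L, 15L, 20L, 25L, 50L, 100L),
                           dGrid = c(1:10, 12L, 16L), sigma = 1 / 8,
                           k = 24L, nRestarts = 100L, seed = 1L) {
    if (!length(mGrid) || !length(dGrid)) stop("grids must be non-empty")
    n <- nrow(x)
    rows <- list()
    for (m in sort(unique(as.integer(mGrid)))) {
        ds <- sort(unique(as.integer(dGrid)))
        ds <- ds[ds <= n - 1L]
        if (m > n - 1L) {
            rows[[length(rows) + 1L]] <- data.frame(m = m, d = ds,
                overallSil = NA_real_, nComponents = NA_integer_,
                status = "m out of range")
            next
        }
        g <- knnGraph(x, m)
        if (nComponents(g) > 1L) {
            rows[[length(rows) + 1L]] <- data.frame(m = m, d = ds,
                overallSil = NA_real_, nComponents = nComponents(g),
                status = "disconnected")
            next
        }
        g <- heatWeights(g, x, sigma)
        op <- graphLaplacian(g)
        emb <- spectralEmbed(op, max(ds), "laplacian",
            list(m = m, d = max(ds), sigma = sigma))
        for (d in ds) {
            cl <- bestKMeans(embeddingCoords(emb)[, seq_len(d), drop = FALSE],
                k, nRestarts = nRestarts, seed = seed)
            rows[[length(rows) + 1L]] <- data.frame(m = m, d = d,
                overallSil = cl@overallSil, nComponents = 1L,
                status = "ok")
        }
    }
    grid <- do.call(rbind, rows)
    ok <- grid$status == "ok" & !is.na(grid$overallSil)
    if (!any(ok))
        stop("every sweep cell was skipped (all graphs disconnected?)")
    cand <- grid[ok, ]
    cand <- cand[order(-cand$overallSil, cand$d, cand$m), ]
    best <- list(m = cand$m[1L], d = cand$d[1L],
        overallSil = cand$overallSil[1L])
    new("SweepResult", grid = grid, best = best)
}

setMethod("show", "SweepResult", function(object) {
    ok <- sum(object@grid$status == "ok")
    cat(sprintf("SweepResult: %d cells (%d evaluated)\n",
        nrow(object@grid), ok))
    cat(sprintf("best: m = %d, d = %d (overall silhouette %.4f)\n",
        object@best$m, object@best$d, object@best$overallSil))
})

#' Write a sweep grid as TSV
#' @param x a \linkS4class{SweepResult}.
#' @param path output path; columns m, d, overall_sil, status.
#' @return \code{path}, invisibly.
#' @export
writeSweep <- function(x, path) {
    g <- x@grid
    names(g) <- c("m", "d", "overall_sil", "n_components", "status")
    utils::write.table(g, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}
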