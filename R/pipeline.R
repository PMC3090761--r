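# End-to-end pipeline: filter -> (hub identification + labeling) ->
# embedding -> best-of-restarts k-means -> silhouette report ->
# enrichment, with every artifact written to a run directory and listed
# in a manifest with content hashes. A single integer seed determines all
# stochastic behavior (restart seeds are derived as seed + restart index).

#' Resolve and validate a pipeline configuration
#'
#' @param method embedding arm: \code{"none"} (cluster the raw vectors),
#'   \code{"pca"}, \code{"laplacian"} or \code{"schroedinger"}.
#' @param m neighbor count for the spectral methods (default 10).
#' @param d target dimension (default 2).
#' @param sigma heat-kernel bandwidth (default 1/8).
#' @param alpha Schroedinger potential strength (default 1).
#' @param k cluster count (default 24).
#' @param nRestarts k-means restarts (default 100).
#' @param seed master seed (default 1).
#' @param labelSource where Schroedinger labels come from: \code{"file"}
#'   (supply \code{labels}), \code{"degree"} or \code{"correlation"}.
#' @param hubCount hubs to label when labels are derived (default 5 for
#'   degree scores, 7 for correlation scores).
#' @param labels character label vector (labelSource = "file").
#' @param logTransform log2-transform a linear-scale matrix before
#'   embedding and clustering? (default TRUE; see [logTransform()])
#' @param filter apply the fold-change gene filter first? (default FALSE)
#' @param foldLow,foldHigh fold-change bounds (defaults 4 and 26).
#' @param fdrThreshold FDR threshold reported by the enrichment stage
#'   (default 0.05).
#' @param fdrMode \code{"per-cluster"} or \code{"global"}.
#' @param beta soft power for correlation connectivity (default 6).
#' @return Validated named list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(method = c("laplacian", "schroedinger", "pca",
                                      "none"),
                           m = 10L, d = 2L, sigma = 1 / 8, alpha = 1,
                           k = 24L, nRestarts = 100L, seed = 1L,
                           labelSource = c("degree", "correlation", "file"),
                           hubCount = NULL, labels = NULL,
                           logTransform = TRUE, filter = FALSE, foldLow = 4, foldHigh = 26,
                           fdrThreshold = 0.05,
                           fdrMode = c("per-cluster", "global"),
                           beta = 6) {
    method <- match.arg(method)
    labelSource <- match.arg(labelSource)
    if (is.null(hubCount))
        hubCount <- if (labelSource == "correlation") 7L else 5L
    cfg <- list(method = method, m = assertCount(m, "m"),
        d = assertCount(d, "d"),
        sigma = assertPositiveScalar(sigma, "sigma"),
        alpha = as.numeric(alpha), k = assertCount(k, "k"),
        nRestarts = assertCount(nRestarts, "nRestarts"),
        seed = as.integer(seed), labelSource = labelSource,
        hubCount = assertCount(hubCount, "hubCount"),
        labels = labels, logTransform = isTRUE(logTransform),
        filter = isTRUE(filter),
        foldLow = as.numeric(foldLow), foldHigh = as.numeric(foldHigh),
        fdrThreshold = as.numeric(fdrThreshold),
        fdrMode = match.arg(fdrMode), beta = as.numeric(beta))
    if (cfg$alpha < 0) stop("'alpha' must be non-negative")
    if (method == "schroedinger" && labelSource == "file" &&
        length(labels) < 2L)
        stop("labelSource = 'file' needs at least 2 labels")
    class(cfg) <- "pipelineConfig"
    cfg
}

runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("stage '%s': %s", stage, conditionMessage(e)),
            call. = FALSE))
}

#' Run the full clustering pipeline
#'
#' Executes filter (optional) -> hub labeling (Schroedinger arm) ->
#' embedding -> best-of-restarts k-means -> silhouette summary ->
#' gene-set enrichment (when \code{sets} given), writing every artifact
#' into \code{outDir} together with the resolved configuration and a
#' manifest of output files with MD5 hashes. Two runs with identical
#' configuration and seed produce byte-identical tables. On a stage
#' error, partial outputs are retained next to a \code{FAILED} marker
#' naming the stage.
#'
#' @param x an \linkS4class{ExpressionMatrix} or path to an expression
#'   TSV.
#' @param config a [pipelineConfig()].
#' @param sets optional \linkS4class{GeneSetCollection} (or GMT path) for
#'   the enrichment stage.
#' @param outDir output directory (created; default a fresh temporary
#'   directory).
#' @param logScale passed to [readExpressionMatrix()] when \code{x} is a
#'   path.
#' @return Invisibly, a list with the fitted objects (\code{matrix},
#'   \code{labels}, \code{embedding}, \code{clustering},
#'   \code{enrichment}) and \code{outDir}.
#' @export
runPipeline <- function(x, config = pipelineConfig(), sets = NULL,
                        outDir = tempfile("generun"), logScale = FALSE) {
    stopifnot(inherits(config, "pipelineConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    failed <- file.path(outDir, "FAILED")
    if (file.exists(failed)) unlink(failed)
    onError <- function(stage, e) {
        writeLines(c(stage, conditionMessage(e)), failed)
        stop(e)
    }
    em <- runStage("input", {
        if (is.character(x)) readExpressionMatrix(x, logScale = logScale)
        else x
    })
    if (is.character(sets)) sets <- runStage("input", readGeneSets(sets))
    cfgPath <- file.path(outDir, "config.json")
    cfgList <- unclass(config)
    cfgList$labels <- as.list(cfgList$labels)
    jsonlite::write_json(cfgList, cfgPath, auto_unbox = TRUE, digits = NA,
        null = "null")

    result <- withCallingHandlers({
        if (config$filter) {
            em <- runStage("filter",
                foldChangeFilter(em, config$foldLow, config$foldHigh))
            writeExpressionMatrix(em,
                file.path(outDir, "expression_filtered.tsv"))
        }
        if (config$logTransform) em <- logTransform(em)
        labels <- NULL
        if (config$method == "schroedinger") {
            labels <- runStage("labeling", {
                if (config$labelSource == "file") {
                    lab <- as.character(config$labels)
                    missing <- setdiff(lab, geneIds(em))
                    if (length(missing))
                        stop(sprintf("labels not in matrix: %s",
                            paste(missing, collapse = ", ")))
                    lab
                } else {
                    scores <- if (config$labelSource == "degree") {
                        g <- heatWeights(knnGraph(em, config$m), em,
                            config$sigma)
                        degreeConnectivity(g)
                    } else {
                        correlationConnectivity(em, beta = config$beta)
                    }
                    utils::write.table(scores,
                        file.path(outDir, "connectivity.tsv"), sep = "\t",
                        quote = FALSE, row.names = FALSE)
                    selectHubs(scores, config$hubCount)
                }
            })
            writeLines(labels, file.path(outDir, "labels.txt"))
        }
        emb <- runStage("embedding", switch(config$method,
            none = identityEmbed(em),
            pca = pcaEmbed(em, d = min(config$d, ncol(em))),
            laplacian = laplacianEigenmaps(em, config$m, config$d,
                config$sigma),
            schroedinger = schroedingerEigenmaps(em, config$m, config$d,
                config$sigma, labels = labels, alpha = config$alpha)))
        writeEmbedding(emb, file.path(outDir, "embedding.tsv"))
        cl <- runStage("clustering", bestKMeans(emb, config$k,
            nRestarts = config$nRestarts, seed = config$seed))
        writeClustering(cl, file.path(outDir, "clustering.tsv"))
        utils::write.table(clusterSummary(cl),
            file.path(outDir, "cluster_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        enr <- NULL
        if (!is.null(sets) && length(sets) > 0L) {
            enr <- runStage("enrichment", enrichAllClusters(cl, sets,
                thresholds = unique(c(config$fdrThreshold,
                    c(0.05, 0.10, 0.15, 0.20))),
                fdrMode = config$fdrMode))
            writeEnrichment(enr, file.path(outDir, "enrichment.tsv"))
        }
        list(matrix = em, labels = labels, embedding = emb,
            clustering = cl, enrichment = enr, outDir = outDir)
    }, error = function(e) onError("pipeline", e))

    files <- setdiff(list.files(outDir), "manifest.json")
    manifest <- list(seed = config$seed,
        configHash = unname(tools::md5sum(cfgPath)),
        files = lapply(stats::setNames(files, files), function(f)
            list(md5 = unname(tools::md5sum(file.path(outDir, f))))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
        auto_unbox = TRUE, digits = NA)
    invisible(result)
}
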