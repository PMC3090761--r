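# Synthetic fixtures with planted structure: everything downstream
# (embedding, clustering, hub detection, enrichment) can be scored against
# ground truth. All generators are pure functions of their arguments and
# the seed.

#' Two side-by-side cone surfaces in 8 dimensions
#'
#' Samples points uniformly (in height and angle) on two right circular
#' cone surfaces whose apexes sit side by side (apex separation twice the
#' base radius), zero-pads the 3-D coordinates to 8 dimensions, applies a
#' seed-fixed random orthogonal rotation, and adds isotropic Gaussian
#' noise. A curved two-class benchmark for nonlinear-versus-linear
#' embeddings: the cones are 2-D surfaces that no linear projection
#' separates cleanly.
#'
#' @param nPoints total number of points (>= 10), split evenly.
#' @param noiseSd isotropic noise standard deviation (default 0.1).
#' @param seed integer seed; fully determines the output.
#' @return List with \code{matrix} (an \linkS4class{ExpressionMatrix},
#'   log-scale), \code{labels} (integer cone membership 1/2),
#'   \code{rotation} (the 8 x 8 orthogonal matrix) and \code{apexOffset}.
#' @examples
#' tc <- generateTwoCones(100, noiseSd = 0, seed = 1)
#' table(tc$labels)
#' @export
generateTwoCones <- function(nPoints, noiseSd = 0.1, seed = 1L) {
    nPoints <- assertCount(nPoints, "nPoints", min = 10L)
    if (noiseSd < 0) stop("'noiseSd' must be non-negative")
    n1 <- ceiling(nPoints / 2); n2 <- nPoints - n1
    apexOffset <- 2   # 2 x base radius 1
    Q <- randomOrthogonal(8L, seed = seed + 1L)
    withSeed(seed, {
        h <- stats::runif(nPoints)
        th <- stats::runif(nPoints, 0, 2 * pi)
        x <- h * cos(th); y <- h * sin(th); z <- h
        x[seq_len(n2) + n1] <- x[seq_len(n2) + n1] + apexOffset
        P <- cbind(x, y, z, matrix(0, nPoints, 5L))
        X <- P %*% Q
        if (noiseSd > 0)
            X <- X + matrix(stats::rnorm(length(X), sd = noiseSd),
                nrow(X), ncol(X))
        ids <- sprintf("p%04d", seq_len(nPoints))
        labels <- rep(c(1L, 2L), c(n1, n2))
        list(matrix = ExpressionMatrix(X, geneIds = ids,
                sampleNames = paste0("t", 1:8), logScale = TRUE),
            labels = stats::setNames(labels, ids),
            rotation = Q, apexOffset = apexOffset)
    })
}

#' Gaussian blobs in a planted 2-D latent plane
#'
#' Places \code{nBlobs} Gaussian clusters at the corners of a regular
#' polygon inside a 2-D latent plane, embeds the plane into 8 dimensions
#' by a seed-fixed orthogonal rotation, and adds small isotropic ambient
#' noise. The cluster geometry genuinely needs two coordinates: any
#' single spectral coordinate collapses distinct blobs, while coordinates
#' beyond the second only add within-cluster spread — the benchmark for
#' target-dimension selection.
#'
#' @param nPoints total number of points, split evenly across blobs.
#' @param nBlobs number of clusters (default 3).
#' @param blobSd within-blob standard deviation in the latent plane
#'   (default 0.1).
#' @param ambientNoiseSd isotropic 8-D noise (default 0.05).
#' @param centers optional nBlobs x 2 matrix of latent blob centers;
#'   default a unit-radius regular polygon.
#' @param seed integer seed.
#' @return List with \code{matrix} (log-scale
#'   \linkS4class{ExpressionMatrix}), \code{labels} and \code{rotation}.
#' @export
generateLatentBlobs <- function(nPoints, nBlobs = 3L, blobSd = 0.1,
                                ambientNoiseSd = 0.05, centers = NULL,
                                seed = 1L) {
    nPoints <- assertCount(nPoints, "nPoints", min = nBlobs)
    nBlobs <- assertCount(nBlobs, "nBlobs", min = 2L)
    if (is.null(centers)) {
        ang <- 2 * pi * (seq_len(nBlobs) - 1L) / nBlobs
        centers <- cbind(cos(ang), sin(ang))
    }
    centers <- as.matrix(centers)
    if (nrow(centers) != nBlobs || ncol(centers) != 2L)
        stop("'centers' must be an nBlobs x 2 matrix")
    Q <- randomOrthogonal(8L, seed = seed + 1L)
    withSeed(seed, {
        labels <- rep(seq_len(nBlobs), length.out = nPoints)
        lat <- centers[labels, , drop = FALSE] +
            matrix(stats::rnorm(2L * nPoints, sd = blobSd), nPoints, 2L)
        X <- cbind(lat, matrix(0, nPoints, 6L)) %*% Q
        if (ambientNoiseSd > 0)
            X <- X + matrix(stats::rnorm(length(X), sd = ambientNoiseSd),
                nrow(X), ncol(X))
        ids <- sprintf("p%04d", seq_len(nPoints))
        list(matrix = ExpressionMatrix(X, geneIds = ids,
                sampleNames = paste0("t", 1:8), logScale = TRUE),
            labels = stats::setNames(labels, ids), rotation = Q)
    })
}

#' Clustered expression time courses with hubs, an inverse cluster and
#' outliers
#'
#' Emulates a developmental time-course experiment: each cluster has a
#' smooth random-walk template profile over the time points and each gene
#' is its cluster template plus Gaussian noise (in log2 space).
#' Designated hub genes carry strongly reduced noise, giving them maximal
#' average within-cluster correlation. Cluster 2's template is the
#' negation of cluster 1's (a repressed/anti-correlated expression
#' pattern), and a 3-gene outlier group with a distinct spike profile is
#' appended. Every gene's log2 profile is affinely rescaled so its
#' max/min fold change on the linear scale lands inside
#' \code{foldRange}; values are returned exponentiated (linear scale,
#' strictly positive).
#'
#' @param nGenes total gene count including the 3 outliers (default 120).
#' @param nClusters number of planted clusters, >= 2 (default 6), not
#'   counting the outlier group.
#' @param nTimepoints number of samples (default 8).
#' @param noiseSd per-gene noise standard deviation in log2 space
#'   (default 0.1); hub genes get \code{0.2 * noiseSd}.
#' @param hubCount designated hubs per cluster (default 3).
#' @param foldRange inclusive per-gene fold-change bounds on the linear
#'   scale (default \code{c(4, 26)}).
#' @param seed integer seed.
#' @return List with \code{matrix} (linear-scale
#'   \linkS4class{ExpressionMatrix}), \code{truth} (data.frame gene_id,
#'   true_cluster, is_hub; outliers carry cluster \code{nClusters + 1}),
#'   \code{hubs} (character ids), \code{sets} (a
#'   \linkS4class{GeneSetCollection} whose categories are the planted
#'   clusters) and \code{templates}.
#' @export
generateClusteredProfiles <- function(nGenes = 120L, nClusters = 6L,
                                      nTimepoints = 8L, noiseSd = 0.1,
                                      hubCount = 3L, foldRange = c(4, 26),
                                      seed = 1L) {
    nGenes <- assertCount(nGenes, "nGenes", min = 10L)
    nClusters <- assertCount(nClusters, "nClusters", min = 2L)
    nTimepoints <- assertCount(nTimepoints, "nTimepoints", min = 3L)
    hubCount <- assertCount(hubCount, "hubCount", min = 0L)
    if (noiseSd < 0) stop("'noiseSd' must be non-negative")
    if (length(foldRange) != 2L || foldRange[1L] < 1 ||
        foldRange[1L] > foldRange[2L])
        stop("'foldRange' must be c(low, high) with 1 <= low <= high")
    nOut <- 3L
    nRegular <- nGenes - nOut
    perCluster <- diff(round(seq(0, nRegular, length.out = nClusters + 1L)))
    if (any(perCluster < max(2L, hubCount)))
        stop("too few genes per cluster for the requested hubCount")
    l2 <- log2(foldRange)
    rMid <- mean(l2)
    jitterSd <- noiseSd * diff(l2) / 8
    withSeed(seed, {
        # smooth random-walk templates, unit sd; cluster 2 mirrors cluster 1
        templates <- replicate(nClusters, {
            w <- cumsum(stats::rnorm(nTimepoints))
            w <- stats::filter(w, rep(1 / 3, 3), sides = 2)
            w[1L] <- w[2L]; w[nTimepoints] <- w[nTimepoints - 1L]
            as.numeric(scale(as.numeric(w)))
        })
        if (nClusters >= 2L) templates[, 2L] <- -templates[, 1L]
        spike <- as.numeric(scale(c(rep(0, floor(nTimepoints / 2) - 1L), 1,
            rep(0, nTimepoints - floor(nTimepoints / 2)))))
        ids <- character(nGenes); clu <- integer(nGenes)
        isHub <- logical(nGenes)
        logX <- matrix(NA_real_, nGenes, nTimepoints)
        g <- 0L
        for (c in seq_len(nClusters)) {
            for (i in seq_len(perCluster[c])) {
                g <- g + 1L
                hub <- i <= hubCount
                sd_g <- noiseSd * if (hub) 0.2 else 1
                p <- templates[, c] + stats::rnorm(nTimepoints, sd = sd_g)
                r <- min(max(rMid + stats::rnorm(1, sd = jitterSd), l2[1L]),
                    l2[2L])
                span <- max(p) - min(p)
                logX[g, ] <- (p - min(p)) / span * r + 6
                ids[g] <- sprintf("c%02d_g%03d", c, i)
                clu[g] <- c; isHub[g] <- hub
            }
        }
        for (i in seq_len(nOut)) {
            g <- g + 1L
            p <- spike + stats::rnorm(nTimepoints, sd = noiseSd * 0.2)
            r <- min(max(rMid + stats::rnorm(1, sd = jitterSd), l2[1L]),
                l2[2L])
            logX[g, ] <- (p - min(p)) / (max(p) - min(p)) * r + 6
            ids[g] <- sprintf("outlier_g%02d", i)
            clu[g] <- nClusters + 1L; isHub[g] <- FALSE
        }
        em <- ExpressionMatrix(2^logX, geneIds = ids,
            sampleNames = paste0("t", seq_len(nTimepoints)),
            logScale = FALSE)
        truth <- data.frame(gene_id = ids, true_cluster = clu,
            is_hub = isHub, stringsAsFactors = FALSE)
        sets <- GeneSetCollection(
            stats::setNames(split(ids, factor(clu, seq_len(nClusters + 1L))),
                c(paste0("planted_", seq_len(nClusters)), "outliers")))
        list(matrix = em, truth = truth, hubs = ids[isHub], sets = sets,
            templates = templates)
    })
}

#' Write a synthetic dataset to disk
#'
#' Writes the expression TSV, the truth table (gene_id, true_cluster,
#' is_hub) and, when present, the planted-cluster GMT, so a simulated
#' dataset can drive the command-line pipeline end to end.
#'
#' @param sim list from [generateClusteredProfiles()],
#'   [generateTwoCones()] or [generateLatentBlobs()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default "synthetic").
#' @return Character vector of the files written, invisibly.
#' @export
writeSyntheticData <- function(sim, dir, prefix = "synthetic") {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    f <- file.path(dir, paste0(prefix, "_expression.tsv"))
    writeExpressionMatrix(sim$matrix, f); files <- c(files, f)
    truth <- if (!is.null(sim$truth)) sim$truth
        else data.frame(gene_id = names(sim$labels),
            true_cluster = unname(sim$labels), is_hub = FALSE,
            stringsAsFactors = FALSE)
    f <- file.path(dir, paste0(prefix, "_truth.tsv"))
    utils::write.table(truth, f, sep = "\t", quote = FALSE,
        row.names = FALSE)
    files <- c(files, f)
    if (!is.null(sim$sets)) {
        f <- file.path(dir, paste0(prefix, "_sets.gmt"))
        writeGeneSets(sim$sets, f); files <- c(files, f)
    }
    invisible(files)
}
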