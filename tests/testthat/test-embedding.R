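test_that("two-node chain solves to lambda = 2, y = (1, -1)", {
    # distance sqrt(log 2) with sigma 1 gives edge weight exactly 1/2,
    # so D = diag(1/2, 1/2) and y = (1, -1) satisfies y^T D y = 1
    em <- ExpressionMatrix(cbind(c(0, sqrt(log(2)))), geneIds = c("a", "b"),
        logScale = TRUE)
    emb <- laplacianEigenmaps(em, m = 1, d = 1, sigma = 1)
    expect_equal(eigenValues(emb), 2, tolerance = 1e-12)
    expect_equal(unname(embeddingCoords(emb)[, 1]), c(1, -1),
        tolerance = 1e-10)
    expect_equal(sum(embeddingCoords(emb)[, 1]^2 * 0.5), 1,
        tolerance = 1e-10)
})

test_that("trivial eigenvalue is excluded and spectra stay positive", {
    em <- randomConnectedMatrix(25, 5, seed = 11)
    emb <- laplacianEigenmaps(em, 5, 4, sigma = 4)
    expect_true(all(eigenValues(emb) > 1e-10))
    expect_true(all(diff(eigenValues(emb)) >= -1e-12))
})

test_that("spectral eigenpairs match a dense generalized-eigenproblem oracle", {
    for (s in 1:5) {
        em <- randomConnectedMatrix(30, 5, seed = 20 + s)
        g <- heatWeights(knnGraph(em, 5), em, sigma = 4)
        op <- graphLaplacian(g)
        emb <- laplacianEigenmaps(em, 5, 3, sigma = 4)
        oracle <- bruteGeneralizedEigen(as.matrix(op@L), op@degree)
        expect_equal(eigenValues(emb), oracle$values[2:4],
            tolerance = 1e-8)
        ang <- subspaceAngle(embeddingCoords(emb),
            oracle$vectors[, 2:4])
        expect_lt(ang, 1e-6)
        # generalized orthogonality y^T D y = I
        G <- t(embeddingCoords(emb)) %*% (op@degree *
            embeddingCoords(emb))
        expect_equal(unname(G), diag(3), tolerance = 1e-8)
    }
})

test_that("sparse eigensolver path agrees with the dense oracle", {
    em <- randomConnectedMatrix(850, 15, seed = 99, D = 3)
    emb <- laplacianEigenmaps(em, 15, 2, sigma = 8)
    g <- heatWeights(knnGraph(em, 15), em, sigma = 8)
    op <- graphLaplacian(g)
    S <- diag(1 / sqrt(op@degree))
    Msym <- S %*% as.matrix(op@L) %*% S
    ev <- sort(eigen(Msym, symmetric = TRUE, only.values = TRUE)$values)
    expect_equal(eigenValues(emb), ev[2:3], tolerance = 1e-8)
})

test_that("the Fiedler coordinate splits two well-separated blobs", {
    for (s in 1:3) {
        X <- withr::with_seed(s, rbind(
            matrix(rnorm(15 * 8, sd = 0.1), 15, 8),
            matrix(rnorm(15 * 8, sd = 0.1) + 3, 15, 8)))
        em <- ExpressionMatrix(X, geneIds = sprintf("g%02d", 1:30),
            logScale = TRUE)
        g <- knnGraph(em, 16)  # force cross-blob edges
        if (nComponents(g) > 1) next
        emb <- laplacianEigenmaps(em, 16, 1, sigma = 8)
        sgn <- sign(embeddingCoords(emb)[, 1])
        expect_true(all(sgn[1:15] == sgn[1]) &&
            all(sgn[16:30] == -sgn[1]))
    }
})

test_that("disconnected graphs error unless the largest component is requested", {
    X <- rbind(matrix(0:3, 4, 8), matrix(100 + (0:3), 4, 8))
    X <- X + withr::with_seed(1, matrix(rnorm(64, sd = 0.01), 8, 8))
    em <- ExpressionMatrix(X, geneIds = letters[1:8], logScale = TRUE)
    expect_error(laplacianEigenmaps(em, 2, 1), "connected components")
    expect_warning(emb <- laplacianEigenmaps(em, 2, 1,
        largestComponent = TRUE), "dropping")
    expect_equal(nrow(embeddingCoords(emb)), 4)
    expect_length(emb@params$dropped, 4)
})

test_that("alpha = 0 Schroedinger reproduces Laplacian Eigenmaps", {
    em <- randomConnectedMatrix(40, 6, seed = 5)
    le <- laplacianEigenmaps(em, 6, 3)
    se <- schroedingerEigenmaps(em, 6, 3, labels = geneIds(em)[c(1, 5, 9)],
        alpha = 0)
    for (j in 1:3) {
        a <- embeddingCoords(le)[, j]; b <- embeddingCoords(se)[, j]
        expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-10)
    }
})

test_that("the label potential contracts labeled genes", {
    # path graph 1-2-3-4: labeling the endpoints pulls them together
    em <- ExpressionMatrix(cbind(0:3), geneIds = as.character(1:4),
        logScale = TRUE)
    d14 <- vapply(c(0, 10), function(a) {
        y <- embeddingCoords(schroedingerEigenmaps(em, 1, 1, sigma = 10,
            labels = c("1", "4"), alpha = a))[, 1]
        abs(y[1] - y[4])
    }, numeric(1))
    expect_lt(d14[2], d14[1])
    # mean pairwise labeled distance non-increasing in alpha
    em50 <- randomConnectedMatrix(50, 8, seed = 3)
    labs <- geneIds(em50)[c(2, 9, 17, 30, 44)]
    meanDist <- vapply(c(0, 0.1, 1, 10), function(a) {
        Y <- embeddingCoords(schroedingerEigenmaps(em50, 8, 2, sigma = 4,
            labels = labs, alpha = a))
        mean(dist(Y[labs, ]))
    }, numeric(1))
    expect_true(all(diff(meanDist) <= 1e-9))
})

test_that("schroedinger input validation lists offending labels", {
    em <- randomConnectedMatrix(20, 4, seed = 2)
    expect_error(schroedingerEigenmaps(em, 4, 2,
        labels = c(geneIds(em)[1], "nope")), "nope")
    expect_error(schroedingerEigenmaps(em, 4, 2,
        labels = geneIds(em)[1]), "at least 2")
    expect_error(schroedingerEigenmaps(em, 4, 2,
        labels = geneIds(em)[1:3], alpha = -1), "non-negative")
})

test_that("PCA embedding matches prcomp and its variance accounting", {
    X <- withr::with_seed(4, matrix(rnorm(100 * 8), 100, 8) %*%
        diag(seq(2, 0.5, length.out = 8)))
    em <- ExpressionMatrix(X, geneIds = sprintf("g%03d", 1:100),
        logScale = TRUE)
    emb <- pcaEmbed(em, d = 8)
    pr <- prcomp(X, center = TRUE, scale. = FALSE)
    for (j in 1:8) {
        a <- embeddingCoords(emb)[, j]; b <- pr$x[, j]
        expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
    }
    shares <- emb@params$varianceShares
    expect_equal(sum(shares), 1, tolerance = 1e-12)
    expect_true(all(diff(shares) <= 1e-12))
    # d = D projection is an isometry
    expect_equal(as.matrix(dist(embeddingCoords(emb))),
        as.matrix(dist(X)), ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("PCA variance-fraction rule picks the smallest sufficient d", {
    # collinear data: one component captures everything
    X <- cbind(1:10, 2 * (1:10)) %*% matrix(rnorm(16, 0.5), 2, 8)
    em <- ExpressionMatrix(X, geneIds = sprintf("g%02d", 1:10),
        logScale = TRUE)
    emb <- pcaEmbed(em, varianceFraction = 0.85)
    expect_identical(ncol(embeddingCoords(emb)), 1L)
    expect_equal(emb@params$varianceShares[1], 1, tolerance = 1e-10)
    expect_error(pcaEmbed(em, d = 9), "ambient dimension")
    flat <- ExpressionMatrix(matrix(1, 5, 8),
        geneIds = letters[1:5], logScale = TRUE)
    expect_error(pcaEmbed(flat, d = 2), "zero total variance")
})
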