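em1d <- function(x, ids = NULL) {
    if (is.null(ids)) ids <- paste0("g", seq_along(x))
    ExpressionMatrix(cbind(x), geneIds = ids, logScale = TRUE)
}

test_that("m-NN graph matches brute-force neighbor sets", {
    g <- knnGraph(em1d(c(0, 1, 3, 7)), m = 1)
    A <- as.matrix(g@adjacency)
    want <- matrix(0, 4, 4)
    want[1, 2] <- want[2, 1] <- 1   # 0-1
    want[2, 3] <- want[3, 2] <- 1   # 1-3
    want[3, 4] <- want[4, 3] <- 1   # 3-7
    expect_equal(unname(A), want)
    # m = n - 1 gives the complete graph
    gc <- knnGraph(em1d(c(0, 1, 3, 7)), m = 3)
    expect_equal(unname(as.matrix(gc@adjacency)),
        matrix(1, 4, 4) - diag(4))
    # coincident points are mutually nearest
    g0 <- knnGraph(em1d(c(0, 0, 5, 9, 14)), m = 1)
    expect_equal(as.matrix(g0@adjacency)[1, 2], 1)
    expect_error(knnGraph(em1d(c(0, 1)), m = 5), "out of range")
})

test_that("heat-kernel weights follow exp(-dist^2/sigma)", {
    # squared distance 1/8 with sigma 1/8 gives exp(-1)
    em <- em1d(c(0, sqrt(1 / 8)))
    g <- heatWeights(knnGraph(em, 1), em, sigma = 1 / 8)
    expect_equal(as.matrix(weightMatrix(g))[1, 2], exp(-1),
        tolerance = 1e-12)
    # coincident endpoints weigh 1
    em0 <- em1d(c(2, 2, 5))
    g0 <- heatWeights(knnGraph(em0, 1), em0)
    expect_equal(as.matrix(weightMatrix(g0))[1, 2], 1)
    expect_error(heatWeights(knnGraph(em0, 1), em0, sigma = 0), "positive")
})

test_that("doubling sigma never decreases any weight", {
    for (s in 1:10) {
        em <- withr::with_seed(s, ExpressionMatrix(matrix(rnorm(160), 20, 8),
            geneIds = sprintf("g%02d", 1:20), logScale = TRUE))
        g <- knnGraph(em, 4)
        w1 <- as.matrix(weightMatrix(heatWeights(g, em, sigma = 1 / 8)))
        w2 <- as.matrix(weightMatrix(heatWeights(g, em, sigma = 1 / 4)))
        expect_true(all(w2 - w1 >= -1e-15))
    }
})

test_that("graph weight matrices stay symmetric with zero diagonal", {
    for (s in 1:10) {
        em <- withr::with_seed(100 + s,
            ExpressionMatrix(matrix(rnorm(30 * 8), 30, 8),
                geneIds = sprintf("g%02d", 1:30), logScale = TRUE))
        g <- heatWeights(knnGraph(em, 3), em)
        W <- as.matrix(weightMatrix(g))
        expect_equal(W, t(W))
        expect_true(all(diag(W) == 0))
        expect_equal(unname(nodeDegrees(g)), unname(rowSums(W)))
        # OR-symmetrization leaves every node with at least one edge
        expect_true(all(rowSums(as.matrix(g@adjacency)) >= 1))
    }
})

test_that("Laplacian is PSD with zero row sums and component null space", {
    em <- em1d(c(0, 1))
    L <- graphLaplacian(heatWeights(knnGraph(em, 1), em, sigma = 1))@L
    w <- exp(-1)
    expect_equal(as.matrix(L), matrix(c(w, -w, -w, w), 2),
        ignore_attr = TRUE)
    for (s in 1:5) {
        em <- withr::with_seed(s, ExpressionMatrix(matrix(rnorm(160), 20, 8),
            geneIds = sprintf("g%02d", 1:20), logScale = TRUE))
        g <- heatWeights(knnGraph(em, 4), em, sigma = 2)
        op <- graphLaplacian(g)
        Ld <- as.matrix(op@L)
        expect_equal(unname(rowSums(Ld)), rep(0, 20), tolerance = 1e-12)
        ev <- eigen(Ld, symmetric = TRUE, only.values = TRUE)$values
        expect_true(all(ev >= -1e-10))
        expect_equal(sum(abs(ev) < 1e-10), nComponents(g))
    }
})

test_that("degree connectivity ranks a star hub first", {
    # star: center at origin, 5 distant satellites pairwise far apart
    X <- rbind(hub = c(0, 0), a = c(1, 0), b = c(-1, 0.05),
        c = c(0, 1.01), d = c(0.02, -1), e = c(0.7, 0.75))
    em <- ExpressionMatrix(X, logScale = TRUE)
    g <- heatWeights(knnGraph(em, 1), em, sigma = 100)
    tab <- degreeConnectivity(g)
    expect_identical(tab$gene_id[1], "hub")
    # handshake identity
    W <- as.matrix(weightMatrix(g))
    expect_equal(sum(tab$score), sum(W))
})

test_that("correlation connectivity equals the brute-force double loop", {
    for (s in 1:5) {
        X <- withr::with_seed(s, matrix(rnorm(30 * 8), 30, 8))
        rownames(X) <- sprintf("g%02d", 1:30)
        tab <- correlationConnectivity(X, beta = 6)
        want <- vapply(1:30, function(i) {
            sum(vapply(setdiff(1:30, i), function(j)
                abs(cor(X[i, ], X[j, ]))^6, numeric(1)))
        }, numeric(1))
        expect_equal(tab$score[match(rownames(X), tab$gene_id)], want,
            tolerance = 1e-12)
    }
    # perfectly correlated pair has adjacency 1 for any beta
    X <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(1, -1, 1, -1.01))
    t2 <- thresholdNetwork(X, beta = 3, tau = 0.999)
    expect_true(any(t2$gene_a == "a" & t2$gene_b == "b"))
    expect_error(correlationConnectivity(
        rbind(a = rep(1, 4), b = 1:4, c = 4:1)), "zero-variance gene")
})

test_that("hub selection is deterministic under score ties", {
    tab <- data.frame(gene_id = c("z", "a", "m"), score = c(3, 3, 1),
        rank = 1:3)
    expect_identical(selectHubs(tab, 1), "a")
    expect_identical(sort(selectHubs(tab, 3)), c("a", "m", "z"))
    expect_error(selectHubs(tab, 4), "exceeds")
})
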