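test_that("k-means solves the separable 1-D example exactly", {
    cl <- lloydKMeans(cbind(c(0, 1, 10, 11)), k = 2, seed = 1)
    a <- clusterAssignment(cl)
    expect_length(unique(a[1:2]), 1)
    expect_length(unique(a[3:4]), 1)
    expect_false(a[1] == a[3])
    expect_equal(cl@objective, 1.0, tolerance = 1e-12)
    expect_equal(sort(as.numeric(clusterCentroids(cl))), c(0.5, 10.5))
})

test_that("k equal to the number of distinct points zeroes the objective", {
    X <- cbind(c(0, 1, 10, 11, 11))   # 4 distinct points
    cl <- lloydKMeans(X, k = 4, seed = 3)
    expect_equal(cl@objective, 0)
    expect_error(lloydKMeans(X, k = 5, seed = 1), "distinct points")
})

test_that("the Lloyd objective is non-increasing across iterations", {
    for (s in 1:100) {
        X <- withr::with_seed(s, matrix(rnorm(40 * 3), 40, 3))
        cl <- lloydKMeans(X, k = 5, seed = s)
        expect_true(all(diff(cl@objectiveTrace) <= 1e-9))
    }
})

test_that("k-means agrees with the stats::kmeans Lloyd oracle from equal starts", {
    for (s in 1:5) {
        X <- withr::with_seed(200 + s, matrix(rnorm(60 * 2), 60, 2))
        cl <- lloydKMeans(X, k = 4, seed = s, maxIter = 200)
        ref <- suppressWarnings(stats::kmeans(X,
            centers = X[withr::with_seed(s, sample(which(!duplicated(X)),
                4)), ], algorithm = "Lloyd", iter.max = 200))
        expect_equal(cl@objective, ref$tot.withinss, tolerance = 1e-8)
    }
})

test_that("row permutation only relabels the clustering", {
    X <- withr::with_seed(9, matrix(rnorm(50 * 2), 50, 2))
    perm <- withr::with_seed(10, sample(50))
    a <- lloydKMeans(X, 3, seed = 4)@assignment
    b <- lloydKMeans(X[perm, ], 3, seed = 4)@assignment
    expect_equal(adjustedRandIndex(a[perm], b), 1)
})

test_that("squared-Euclidean silhouette reproduces the hand example", {
    sil <- sqSilhouette(cbind(c(0, 1, 10, 11)), c(1, 1, 2, 2))
    expect_equal(sil$perPoint,
        c(109.5 / 110.5, 89.5 / 90.5, 89.5 / 90.5, 109.5 / 110.5),
        tolerance = 1e-12)
    expect_equal(sil$overall, 0.989950251243719, tolerance = 1e-12)
    expect_error(sqSilhouette(cbind(1:4), rep(1, 4)), "single cluster")
})

test_that("silhouette matches the brute-force oracle on random instances", {
    for (s in 1:20) {
        X <- withr::with_seed(s, matrix(rnorm(25 * 3), 25, 3))
        a <- withr::with_seed(s + 500, sample(1:4, 25, replace = TRUE))
        if (length(unique(a)) < 2) next
        got <- sqSilhouette(X, a)
        want <- bruteSilhouette(X, a)
        expect_equal(got$perPoint, want$perPoint, tolerance = 1e-12)
        expect_equal(got$overall, want$overall, tolerance = 1e-12)
    }
})

test_that("silhouette is isometry-invariant and punishes coincident clusters", {
    X <- withr::with_seed(2, matrix(rnorm(20 * 2), 20, 2))
    a <- rep(1:2, 10)
    base <- sqSilhouette(X, a)$overall
    th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    expect_equal(sqSilhouette(X %*% R + 5, a)$overall, base,
        tolerance = 1e-12)
    # identical point sets in both clusters: B <= A everywhere
    Y <- rbind(X[1:10, ], X[1:10, ])
    expect_true(all(sqSilhouette(Y, rep(1:2, each = 10))$perPoint <= 0))
})

test_that("restart selection returns the max-silhouette run, reproducibly", {
    X <- withr::with_seed(12, rbind(matrix(rnorm(60, sd = 0.3), 30, 2),
        matrix(rnorm(60, sd = 0.3) + 4, 30, 2)))
    one <- lloydKMeans(X, 3, seed = 7)
    b1 <- bestKMeans(X, 3, nRestarts = 1, seed = 7)
    expect_identical(b1@assignment, one@assignment)
    b <- bestKMeans(X, 3, nRestarts = 15, seed = 7)
    expect_equal(b@overallSil, max(b@restartSil))
    b2 <- bestKMeans(X, 3, nRestarts = 15, seed = 7)
    expect_identical(b@assignment, b2@assignment)
    expect_identical(b@restartSil, b2@restartSil)
})

test_that("best-of-restarts recovers planted blobs", {
    for (s in 1:10) {
        ctr <- matrix(c(0, 0, 8, 0, 0, 8, 8, 8), 4, 2, byrow = TRUE)
        lab <- rep(1:4, each = 15)
        X <- withr::with_seed(s, ctr[lab, ] + matrix(rnorm(120, sd = 0.4),
            60, 2))
        cl <- bestKMeans(X, 4, nRestarts = 20, seed = s)
        expect_equal(adjustedRandIndex(cl@assignment, lab), 1)
    }
})

test_that("average linkage reproduces the hand-computed dendrogram", {
    h <- averageLinkage(cbind(c(0, 1, 10)))
    expect_equal(h$height, c(1, 9.5))
    expect_identical(unname(cutDendrogram(h, k = 3)), 1:3)
    for (s in 1:10) {
        X <- withr::with_seed(s, matrix(rnorm(20 * 2), 20, 2))
        expect_true(all(diff(averageLinkage(X)$height) >= -1e-12))
    }
    expect_error(averageLinkage(cbind(1)), "at least 2")
})

test_that("adjusted Rand index behaves at its reference points", {
    a <- rep(1:3, 10)
    expect_equal(adjustedRandIndex(a, a), 1)
    expect_equal(adjustedRandIndex(a, c(3, 1, 2)[a]), 1)  # relabeling
    means <- vapply(1:100, function(s) withr::with_seed(s, {
        adjustedRandIndex(sample(1:5, 200, TRUE), sample(1:5, 200, TRUE))
    }), numeric(1))
    expect_lt(abs(mean(means)), 0.05)
    expect_error(adjustedRandIndex(1:3, 1:4), "equal length")
})

test_that("cluster summary has the per-cluster report shape", {
    cl <- lloydKMeans(cbind(c(0, 1, 10, 11)), k = 2, seed = 1)
    s <- clusterSummary(cl)
    expect_identical(names(s), c("cluster", "size", "sil"))
    expect_identical(s$size, c(2L, 2L))
    expect_equal(mean(s$sil), cl@overallSil, tolerance = 1e-12)
})
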