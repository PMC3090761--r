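test_that("Fisher tail handles its degenerate endpoints", {
    uni <- paste0("g", 1:50)
    sets <- GeneSetCollection(list(A = uni[1:10], B = uni[41:45]))
    # no overlap: P(X >= 0) = 1
    t1 <- fisherEnrichment(uni[11:20], sets, uni)
    expect_equal(t1$pValue[t1$category == "B"], 1)
    # cluster = universe: overlap is certain
    t2 <- fisherEnrichment(uni, sets, uni)
    expect_equal(t2$pValue, c(1, 1))
    expect_error(fisherEnrichment(c("zzz"), sets, uni), "outside")
    expect_error(fisherEnrichment("g1", sets, character(0)), "empty")
})

test_that("Fisher p equals the combinatorial enumeration oracle", {
    # the worked configuration: 100 genes, category 10, cluster 10, overlap 5
    uni <- paste0("g", 1:100)
    sets <- GeneSetCollection(list(A = uni[1:10]))
    tab <- fisherEnrichment(c(uni[1:5], uni[90:94]), sets, uni)
    expect_equal(tab$pValue, bruteFisherTail(5, 10, 100, 10),
        tolerance = 1e-12)
    # sweep of configurations with population <= 60
    for (N in c(11, 23, 60)) {
        for (K in c(2, 5, N %/% 2)) {
            for (n in c(3, N %/% 3)) {
                uni <- paste0("g", seq_len(N))
                sets <- GeneSetCollection(list(S = uni[seq_len(K)]))
                for (q in 0:min(K, n)) {
                    clu <- c(uni[seq_len(q)],
                        uni[K + seq_len(n - q)])
                    p <- fisherEnrichment(clu, sets, uni)$pValue
                    expect_equal(p, bruteFisherTail(q, K, N, n),
                        tolerance = 1e-12)
                }
            }
        }
    }
})

test_that("Benjamini-Hochberg q-values follow the step-up rule", {
    expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(fdrAdjust(0.37), 0.37)
    p <- c(0.04, 0.001, 0.5, 0.2, 0.013)
    perm <- c(3, 1, 5, 2, 4)
    expect_equal(fdrAdjust(p)[perm], fdrAdjust(p[perm]))
    expect_error(fdrAdjust(c(0.1, 0)), "in \\(0, 1\\]")
    expect_error(fdrAdjust(numeric(0)), "empty")
})

test_that("planted category overlap dominates a cluster's enrichment", {
    withr::with_seed(31, {
        uni <- paste0("g", 1:200)
        sets <- GeneSetCollection(list(
            planted = uni[1:25],
            decoy1 = sample(uni, 30), decoy2 = sample(uni, 12),
            decoy3 = sample(uni, 40)))
        # cluster 1 is built from the planted category
        assign <- c(rep(1L, 25), rep(2:4, length.out = 175))
        cl <- new("GeneClustering", geneIds = uni,
            assignment = assign, k = 4L,
            centroids = matrix(0, 4, 1), objective = 0,
            objectiveTrace = 0, perPointSil = numeric(200),
            perClusterSil = numeric(0), overallSil = NA_real_,
            seed = 1L, nRestarts = 1L, restartSil = NA_real_)
        enr <- enrichAllClusters(cl, sets)
        t1 <- enrichmentResults(enr)
        best <- t1[t1$cluster == 1, ][1, ]
        expect_identical(best$category, "planted")
        expect_lt(best$qValue, 0.05)
    })
})

test_that("enriched counts are monotone in the FDR threshold", {
    withr::with_seed(17, {
        uni <- paste0("g", 1:150)
        sets <- GeneSetCollection(lapply(
            setNames(1:8, paste0("S", 1:8)),
            function(i) sample(uni, 10 + i)))
        assign <- sample(1:5, 150, replace = TRUE)
        cl <- new("GeneClustering", geneIds = uni,
            assignment = as.integer(assign), k = 5L,
            centroids = matrix(0, 5, 1), objective = 0,
            objectiveTrace = 0, perPointSil = numeric(150),
            perClusterSil = numeric(0), overallSil = NA_real_,
            seed = 1L, nRestarts = 1L, restartSil = NA_real_)
        enr <- enrichAllClusters(cl, sets,
            thresholds = c(0.05, 0.10, 0.15, 0.20, 1))
        counts <- vapply(c(0.05, 0.10, 0.15, 0.20, 1),
            function(th) enrichedCount(enr, th), integer(1))
        expect_true(all(diff(counts) >= 0))
        # threshold 1 counts every tested pair (q <= 1, strict < handled)
        expect_equal(counts[5], sum(enrichmentResults(enr)$qValue < 1))
        # global pooling yields q-values from one family
        eg <- enrichAllClusters(cl, sets, fdrMode = "global")
        expect_equal(enrichmentResults(eg)$qValue,
            fdrAdjust(enrichmentResults(eg)$pValue))
    })
})

test_that("categories below the minimum size are skipped", {
    uni <- paste0("g", 1:30)
    sets <- GeneSetCollection(list(tiny = c("g1", "nope"),
        ok = uni[1:5]))
    tab <- fisherEnrichment(uni[1:3], sets, uni)
    expect_identical(tab$category, "ok")
})

test_that("uniform-null p-values are not anti-conservative", {
    withr::with_seed(77, {
        uni <- paste0("g", 1:300)
        ps <- replicate(40, {
            sets <- GeneSetCollection(list(S = sample(uni, 30)))
            fisherEnrichment(sample(uni, 40), sets, uni)$pValue
        })
        frac <- mean(ps < 0.05)
        sdHat <- sqrt(0.05 * 0.95 / length(ps))
        expect_lte(frac, 0.05 + 3 * sdHat)
    })
})
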