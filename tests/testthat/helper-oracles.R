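# Independent oracles and fixture builders shared across tests. These
# deliberately use naive formulations (double loops, enumeration, dense
# algebra) so they cannot share a code path with the implementation.

# Brute-force O(n^2) squared-Euclidean silhouette.
bruteSilhouette <- function(X, assignment) {
    n <- nrow(X)
    d2 <- function(i, j) sum((X[i, ] - X[j, ])^2)
    sil <- numeric(n)
    for (i in seq_len(n)) {
        own <- setdiff(which(assignment == assignment[i]), i)
        if (!length(own)) { sil[i] <- 0; next }
        A <- mean(vapply(own, function(j) d2(i, j), numeric(1)))
        B <- Inf
        for (cl in setdiff(unique(assignment), assignment[i])) {
            members <- which(assignment == cl)
            B <- min(B, mean(vapply(members, function(j) d2(i, j),
                numeric(1))))
        }
        sil[i] <- if (max(A, B) > 0) (B - A) / max(A, B) else 0
    }
    list(perPoint = sil, overall = mean(sil))
}

# Exact hypergeometric upper tail by direct enumeration of binomial
# coefficients: P(X >= q) drawing n from N with K successes.
bruteFisherTail <- function(q, K, N, n) {
    js <- seq.int(max(q, 0L), min(K, n))
    if (!length(js)) return(0)
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Dense generalized eigenproblem L x = lambda D x solved independently of
# the package path (non-symmetric dense solve).
bruteGeneralizedEigen <- function(L, deg) {
    M <- diag(1 / deg) %*% L
    e <- eigen(M)
    ord <- order(Re(e$values))
    list(values = Re(e$values)[ord],
        vectors = Re(e$vectors)[, ord, drop = FALSE])
}

# Random expression-like matrix whose m-NN graph is connected (resamples
# until it is).
randomConnectedMatrix <- function(n, m, seed, D = 8) {
    for (try in 0:50) {
        X <- withr::with_seed(seed + 1000L * try,
            matrix(stats::rnorm(n * D), n, D))
        em <- ExpressionMatrix(X, geneIds = sprintf("g%03d", seq_len(n)),
            logScale = TRUE)
        if (nComponents(knnGraph(em, m)) == 1L) return(em)
    }
    stop("could not build a connected instance")
}

# Largest principal angle (radians) between the column spaces of two
# matrices with orthonormalized columns.
subspaceAngle <- function(A, B) {
    qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
    sv <- svd(crossprod(qa, qb))$d
    acos(min(1, max(0, min(sv))))
}
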