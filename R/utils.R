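# internal helpers shared across modules

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# random stream.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

# All pairwise squared Euclidean distances between rows of X (n x n dense).
# Clamped at zero: the crossprod identity can go slightly negative in
# floating point for near-coincident rows.
squaredDistanceMatrix <- function(X) {
    sq <- rowSums(X^2)
    D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
    D2[D2 < 0] <- 0
    diag(D2) <- 0
    D2
}

# Squared distances between rows of X (n x dim) and rows of C (k x dim).
crossSquaredDistance <- function(X, C) {
    D2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * tcrossprod(X, C)
    D2[D2 < 0] <- 0
    D2
}

# Seeded random orthogonal matrix (QR of a Gaussian matrix, sign-fixed so
# the factorization is unique and reproducible).
randomOrthogonal <- function(p, seed) {
    withSeed(seed, {
        qr <- qr(matrix(stats::rnorm(p * p), p, p))
        Q <- qr.Q(qr)
        Q %*% diag(sign(diag(qr.R(qr))), p)
    })
}

# Deterministic per-column sign convention: the entry of largest magnitude
# in each column is made positive (first index wins ties).
fixColumnSigns <- function(Y) {
    for (j in seq_len(ncol(Y))) {
        i <- which.max(abs(Y[, j]))
        if (Y[i, j] < 0) Y[, j] <- -Y[, j]
    }
    Y
}

assertCount <- function(x, name, min = 1L) {
    if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x))
        stop(sprintf("'%s' must be a single integer >= %d", name, min),
            call. = FALSE)
    as.integer(x)
}

assertPositiveScalar <- function(x, name) {
    if (length(x) != 1L || !is.finite(x) || x <= 0)
        stop(sprintf("'%s' must be a single positive number", name),
            call. = FALSE)
    as.numeric(x)
}
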