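# Independent brute-force oracles. Deliberately literal, loop-based
# implementations that the vectorized package code is checked against.

# Straight-loop FCM: literally alternates the center and membership
# update formulas from a supplied initial membership matrix, checking
# the max absolute membership change against delta.
oracleFCM <- function(X, U0, m, delta, maxIter) {
    X <- as.matrix(X)
    U <- as.matrix(U0)
    M <- nrow(X); cc <- ncol(U)
    for (q in seq_len(maxIter)) {
        V <- matrix(0, cc, ncol(X))
        for (k in seq_len(cc)) {
            num <- 0; den <- 0
            for (i in seq_len(M)) {
                num <- num + U[i, k]^m * X[i, ]
                den <- den + U[i, k]^m
            }
            V[k, ] <- num / den
        }
        Unew <- matrix(0, M, cc)
        for (i in seq_len(M)) {
            dd <- sapply(seq_len(cc), function(k)
                sqrt(sum((X[i, ] - V[k, ])^2)))
            if (any(dd < 1e-12)) {
                hit <- dd < 1e-12
                Unew[i, hit] <- 1 / sum(hit)
            } else {
                for (k in seq_len(cc))
                    Unew[i, k] <- 1 / sum((dd[k] / dd)^(2 / (m - 1)))
            }
        }
        done <- max(abs(U - Unew)) <= delta
        U <- Unew
        if (done) break
    }
    list(U = U, V = V, iterations = q)
}

# Exhaustive max-min composition over clusters.
oracleMaxMin <- function(U) {
    M <- nrow(U)
    Fm <- matrix(0, M, M)
    for (i in seq_len(M))
        for (j in seq_len(M)) {
            best <- 0
            for (k in seq_len(ncol(U)))
                best <- max(best, min(U[i, k], U[j, k]))
            Fm[i, j] <- best
        }
    diag(Fm) <- 1
    Fm
}

# Brute-force co-occurrence counting by explicit pixel-pair enumeration.
oracleGLCMCounts <- function(gray, nLevels, dr, dc, symmetric = TRUE) {
    L <- pmin(pmax(floor(gray * nLevels) + 1L, 1L), nLevels)
    cnt <- matrix(0L, nLevels, nLevels)
    for (r in seq_len(nrow(L)))
        for (c in seq_len(ncol(L))) {
            r2 <- r + dr; c2 <- c + dc
            if (r2 >= 1 && r2 <= nrow(L) && c2 >= 1 && c2 <= ncol(L)) {
                cnt[L[r, c], L[r2, c2]] <- cnt[L[r, c], L[r2, c2]] + 1L
                if (symmetric)
                    cnt[L[r2, c2], L[r, c]] <- cnt[L[r2, c2], L[r, c]] + 1L
            }
        }
    cnt
}

# Scalar-by-scalar evaluation of one LSTM step from the gate equations,
# written without any of the package's matrix machinery.
oracleLSTMStep <- function(Wi, Wr, b, z, hPrev, cPrev, H) {
    sig <- function(x) 1 / (1 + exp(-x))
    pre <- as.numeric(Wi %*% z + Wr %*% hPrev + b)
    u <- sig(pre[1:H])
    f <- sig(pre[(H + 1):(2 * H)])
    w <- tanh(pre[(2 * H + 1):(3 * H)])
    e <- sig(pre[(3 * H + 1):(4 * H)])
    cNew <- f * cPrev + u * w
    list(h = e * tanh(cNew), c = cNew)
}

# Shared small fixtures
sixPoints <- c(1, 2, 3, 11, 12, 13)
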