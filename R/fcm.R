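#' Construct a fuzzy c-means configuration
#'
#' @param c number of clusters (integer >= 1; the degenerate \code{c = 1}
#'   gives every point membership 1 in a single cluster at the mean).
#' @param m fuzzy weighting exponent, > 1. Larger values give softer
#'   partitions; 2 is the field's standard default.
#' @param delta convergence threshold: iteration stops when the maximum
#'   absolute elementwise change of the membership matrix is <= delta.
#' @param maxIter maximum number of update iterations.
#' @param seed RNG seed for the Dirichlet(1, ..., 1) row-wise random
#'   initialization of the membership matrix.
#' @return An \linkS4class{FCMConfig} object.
#' @examples
#' fcmConfig(c = 3)
#' @export
fcmConfig <- function(c = 3L, m = 2, delta = 1e-5, maxIter = 100L,
                      seed = 1L) {
    new("FCMConfig", c = as.integer(c), m = as.numeric(m),
        delta = as.numeric(delta), maxIter = as.integer(maxIter),
        seed = as.integer(seed))
}

#' Fuzzy c-means clustering
#'
#' Soft clustering minimizing the weighted within-cluster squared
#' Euclidean distance \eqn{\sum_i \sum_k \mu_{ik}^m \|s_i - v_k\|^2}
#' subject to each point's memberships summing to 1. Cluster centers are
#' the membership-weighted means of the points and memberships are the
#' inverse-distance-ratio update, alternated until the membership matrix
#' changes by at most \code{delta} (maximum absolute elementwise
#' difference) or the iteration cap is reached.
#'
#' The membership matrix is initialized row-wise from a symmetric
#' Dirichlet(1, ..., 1) distribution using the configured seed. If a
#' point coincides with one or more centers (distance < 1e-12) its
#' membership is split equally over the coincident centers and is 0
#' elsewhere. After fitting, clusters are relabelled deterministically:
#' ascending by center value for scalar data, or by the centers' first
#' principal coordinate for multivariate data.
#'
#' @param x numeric vector (scalar points) or matrix with one point per
#'   row.
#' @param config an \linkS4class{FCMConfig}.
#' @return A \linkS4class{FuzzyPartition}.
#' @examples
#' p <- fcmFit(c(0, 0, 10, 10), fcmConfig(c = 2, seed = 7))
#' centers(p)
#' @seealso \code{\link{updateCenters}}, \code{\link{updateMemberships}},
#'   \code{\link{fcmObjective}}
#' @export
fcmFit <- function(x, config = fcmConfig()) {
    X <- asPointMatrix(x)
    validObject(config)
    M <- nrow(X)
    c <- config@c
    nDistinct <- nrow(unique(X))
    if (c > nDistinct)
        stop(sprintf(
            "c = %d exceeds the number of distinct points (%d)", c,
            nDistinct), call. = FALSE)

    if (c == 1L) {
        U <- matrix(1, M, 1L)
        V <- matrix(colMeans(X), 1L)
        obj <- fcmObjective(X, V, U, config@m)
        return(new("FuzzyPartition", memberships = U, centers = V,
            nIterations = 0L, converged = TRUE, objectiveTrace = obj))
    }

    ## Dirichlet(1,...,1) rows via normalized exponentials
    U <- withSeed(config@seed, {
        E <- matrix(stats::rexp(M * c), M, c)
        E / rowSums(E)
    })

    trace <- numeric(0)
    convergedFlag <- FALSE
    q <- 0L
    for (q in seq_len(config@maxIter)) {
        V <- updateCenters(X, U, config@m)
        Unew <- updateMemberships(X, V, config@m)
        trace <- c(trace, fcmObjective(X, V, Unew, config@m))
        deltaU <- max(abs(U - Unew))
        U <- Unew
        if (deltaU <= config@delta) {
            convergedFlag <- TRUE
            break
        }
    }

    ord <- clusterOrder(V)
    new("FuzzyPartition",
        memberships = U[, ord, drop = FALSE],
        centers = V[ord, , drop = FALSE],
        nIterations = q,
        converged = convergedFlag,
        objectiveTrace = trace)
}

## Deterministic cluster relabelling: ascending center value in 1-D,
## ascending first principal coordinate otherwise (sign fixed so the
## largest-magnitude loading is positive).
clusterOrder <- function(V) {
    if (ncol(V) == 1L) return(order(V[, 1L]))
    Vc <- scale(V, center = TRUE, scale = FALSE)
    sv <- svd(Vc, nu = 0L, nv = 1L)
    v1 <- sv$v[, 1L]
    if (v1[which.max(abs(v1))] < 0) v1 <- -v1
    order(drop(Vc %*% v1))
}

#' Cluster-center update
#'
#' Each center is the mean of all points weighted by the m-th power of
#' their memberships, so every center lies in the convex hull of the data.
#'
#' @param x points (vector or matrix, one point per row).
#' @param memberships row-normalized membership matrix (points x clusters).
#' @param m fuzzy exponent (> 1).
#' @return Matrix of centers, clusters x dimension.
#' @export
updateCenters <- function(x, memberships, m) {
    X <- asPointMatrix(x)
    U <- as.matrix(memberships)
    if (nrow(U) != nrow(X))
        stop("memberships must have one row per point", call. = FALSE)
    Um <- U^m
    mass <- colSums(Um)
    if (any(mass <= 0))
        stop("cluster with zero membership mass", call. = FALSE)
    sweep(t(Um) %*% X, 1L, mass, "/")
}

#' Membership update
#'
#' The inverse-distance-ratio rule: the membership of point i in cluster
#' k is \eqn{1 / \sum_j (\|s_i - v_k\| / \|s_i - v_j\|)^{2/(m-1)}}.
#' A point within 1e-12 of one or more centers receives membership split
#' equally over the coincident centers (0 elsewhere), so the rule is
#' never evaluated with a zero denominator.
#'
#' @param x points (vector or matrix, one point per row).
#' @param centers matrix of cluster centers (clusters x dimension).
#' @param m fuzzy exponent (> 1).
#' @return Membership matrix, points x clusters, rows summing to 1.
#' @export
updateMemberships <- function(x, centers, m) {
    X <- asPointMatrix(x)
    V <- asPointMatrix(centers)
    if (ncol(V) != ncol(X))
        stop("points and centers must share a dimension", call. = FALSE)
    D <- euclideanDistances(X, V)
    coincTol <- 1e-12
    p <- 2 / (m - 1)
    U <- matrix(0, nrow(X), nrow(V))
    hit <- D < coincTol
    anyHit <- rowSums(hit) > 0
    if (any(anyHit))
        U[anyHit, ] <- hit[anyHit, , drop = FALSE] /
            rowSums(hit[anyHit, , drop = FALSE])
    if (any(!anyHit)) {
        W <- D[!anyHit, , drop = FALSE]^(-p)
        U[!anyHit, ] <- W / rowSums(W)
    }
    U
}

euclideanDistances <- function(X, V) {
    ## points x centers Euclidean distance matrix
    d2 <- outer(rowSums(X^2), rep(1, nrow(V))) +
        outer(rep(1, nrow(X)), rowSums(V^2)) - 2 * X %*% t(V)
    sqrt(pmax(d2, 0))
}

#' Fuzzy c-means objective value
#'
#' The weighted within-cluster sum of squared Euclidean distances,
#' \eqn{\sum_i \sum_k \mu_{ik}^m \|s_i - v_k\|^2}. The alternating
#' center/membership updates make this non-increasing across iterations.
#'
#' @param x points (vector or matrix, one point per row).
#' @param centers cluster centers (clusters x dimension).
#' @param memberships membership matrix (points x clusters).
#' @param m fuzzy exponent.
#' @return numeric(1) objective value.
#' @export
fcmObjective <- function(x, centers, memberships, m) {
    X <- asPointMatrix(x)
    V <- asPointMatrix(centers)
    U <- as.matrix(memberships)
    D <- euclideanDistances(X, V)
    sum(U^m * D^2)
}

#' Serialize / restore a fuzzy partition
#'
#' \code{writeFuzzyPartition} writes a partition as a JSON metadata file
#' plus a CSV membership matrix next to it; \code{readFuzzyPartition}
#' restores the object. Used for pipeline caching.
#'
#' @param partition a \linkS4class{FuzzyPartition}.
#' @param path path of the JSON file to write (the membership CSV gets the
#'   same path with extension \code{.csv}).
#' @return \code{writeFuzzyPartition} returns \code{path} invisibly;
#'   \code{readFuzzyPartition} returns the restored
#'   \linkS4class{FuzzyPartition}.
#' @export
writeFuzzyPartition <- function(partition, path) {
    stopifnot(is(partition, "FuzzyPartition"))
    csv <- sub("\\.json$", ".csv", path)
    if (identical(csv, path)) csv <- paste0(path, ".csv")
    meta <- list(
        centers = partition@centers,
        nIterations = partition@nIterations,
        converged = partition@converged,
        objectiveTrace = partition@objectiveTrace,
        membershipsFile = basename(csv)
    )
    jsonlite::write_json(meta, path, digits = NA, auto_unbox = TRUE)
    utils::write.csv(partition@memberships, csv, row.names = FALSE)
    invisible(path)
}

#' @rdname writeFuzzyPartition
#' @export
readFuzzyPartition <- function(path) {
    meta <- jsonlite::read_json(path, simplifyVector = TRUE)
    csv <- file.path(dirname(path), meta$membershipsFile)
    U <- as.matrix(utils::read.csv(csv))
    dimnames(U) <- NULL
    new("FuzzyPartition",
        memberships = U,
        centers = as.matrix(meta$centers),
        nIterations = as.integer(meta$nIterations),
        converged = as.logical(meta$converged),
        objectiveTrace = as.numeric(meta$objectiveTrace))
}
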