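#' Compress a feature vector into a short sequence of cluster centers
#'
#' Runs scalar fuzzy c-means on the N values of a flattened feature
#' vector, treating each value as a 1-D point, and returns the \code{n}
#' fitted cluster centers as a short sequence. This is the compression
#' step that turns a long flattened deep-feature vector into a sequence
#' short enough for recurrence-plot construction (default \code{n = 13}).
#'
#' @param g numeric feature vector of length N (N >= n).
#' @param n number of clusters, i.e. the compressed length.
#' @param config \linkS4class{FCMConfig} for the compression run; its
#'   \code{c} slot is overridden by \code{n}.
#' @param order \code{"sorted"} (default) returns centers ascending by
#'   value, a permutation-invariant, reproducible convention;
#'   \code{"assignment"} orders clusters by the position of the first
#'   feature value whose largest membership falls in each cluster.
#' @return numeric vector of length \code{n}.
#' @examples
#' g <- c(rnorm(50), rnorm(50, 10))
#' compressSequence(g, n = 2, config = fcmConfig(c = 2, seed = 1))
#' @export
compressSequence <- function(g, n = 13L,
                             config = fcmConfig(c = n, m = 2,
                                 delta = 1e-5, maxIter = 100L),
                             order = c("sorted", "assignment")) {
    order <- match.arg(order)
    g <- as.numeric(g)
    stopIfNotFinite(g, "feature vector")
    n <- as.integer(n)
    if (n > length(g))
        stop(sprintf("n = %d exceeds feature length N = %d", n, length(g)),
            call. = FALSE)
    ## degenerate constant vector: every center coincides with the value
    if (length(unique(g)) == 1L) return(rep(g[1], n))
    cfg <- new("FCMConfig", c = n, m = config@m, delta = config@delta,
        maxIter = config@maxIter, seed = config@seed)
    fit <- fcmFit(g, cfg)
    ctr <- drop(centers(fit))
    if (order == "sorted") return(sort(ctr))
    ## assignment order: clusters by first appearance of their hard assignment
    hard <- max.col(memberships(fit), ties.method = "first")
    first <- vapply(seq_len(n), function(k) {
        ix <- which(hard == k)
        if (length(ix)) min(ix) else length(g) + k
    }, numeric(1))
    ctr[order(first)]
}

#' Time-delay embedding of a scalar sequence
#'
#' Reconstructs a phase space from a scalar sequence using lagged
#' copies: state i is \eqn{(x_i, x_{i+\tau}, ..., x_{i+(d-1)\tau})},
#' giving \eqn{M = n - (d-1)\tau} states of dimension d.
#'
#' @param x numeric sequence of length n.
#' @param d embedding dimension (integer >= 1).
#' @param tau time delay (integer >= 1).
#' @return numeric matrix with M rows (states) and d columns.
#' @examples
#' embedSequence(1:5, d = 2, tau = 1)
#' @export
embedSequence <- function(x, d = 1L, tau = 1L) {
    x <- as.numeric(x)
    stopIfNotFinite(x, "sequence")
    d <- as.integer(d); tau <- as.integer(tau)
    if (d < 1L || tau < 1L)
        stop("d and tau must be integers >= 1", call. = FALSE)
    M <- length(x) - (d - 1L) * tau
    if (M < 2L)
        stop(sprintf(
            "embedding leaves M = %d states; need at least 2 (n = %d, d = %d, tau = %d)",
            M, length(x), d, tau), call. = FALSE)
    S <- vapply(seq_len(d), function(j) x[seq_len(M) + (j - 1L) * tau],
        numeric(M))
    matrix(S, nrow = M, ncol = d)
}

#' Max-min fuzzy relation composition
#'
#' Given a membership matrix U (states x clusters), returns the square
#' fuzzy similarity matrix whose (i, j) entry is
#' \eqn{\max_k \min(U_{ik}, U_{jk})} for \eqn{i \neq j} (transitivity via
#' the cluster centers, using the symmetry of the state-center grades),
#' with the diagonal set to exactly 1 (reflexivity).
#'
#' @param U numeric membership matrix with entries in [0, 1].
#' @return symmetric matrix with unit diagonal and entries in [0, 1].
#' @examples
#' U <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.6, 0.4))
#' maxMinCompose(U)
#' @export
maxMinCompose <- function(U) {
    U <- as.matrix(U)
    stopIfNotFinite(U, "membership matrix")
    M <- nrow(U)
    Fm <- matrix(0, M, M)
    for (k in seq_len(ncol(U)))
        Fm <- pmax(Fm, outer(U[, k], U[, k], pmin))
    diag(Fm) <- 1
    Fm
}

#' Build a fuzzy recurrence plot from a phase space
#'
#' Clusters the embedded states with fuzzy c-means (\code{c} clusters,
#' exponent \code{m}) and composes the state-to-state fuzzy similarity
#' grades by the max-min rule over the cluster memberships. The result is
#' a symmetric M x M matrix with unit diagonal and entries in [0, 1] — a
#' grayscale generalization of a binary recurrence plot.
#'
#' @param S phase space: numeric matrix (states x dimension) from
#'   \code{\link{embedSequence}}, or a numeric vector (dimension-1
#'   states).
#' @param c number of FCM clusters (>= 2, <= number of states).
#' @param m fuzzy exponent.
#' @param delta,maxIter,seed FCM convergence threshold, iteration cap and
#'   initialization seed (see \code{\link{fcmConfig}}).
#' @return An \linkS4class{FRP}.
#' @examples
#' S <- embedSequence(sin(1:20), d = 2, tau = 1)
#' buildFRP(S, c = 3, seed = 1)
#' @export
buildFRP <- function(S, c = 3L, m = 2, delta = 1e-5, maxIter = 100L,
                     seed = 1L) {
    S <- asPointMatrix(S)
    c <- as.integer(c)
    if (c < 2L)
        stop("FRP construction needs c >= 2 clusters", call. = FALSE)
    if (nrow(S) < c)
        stop(sprintf("M = %d states is fewer than c = %d clusters",
            nrow(S), c), call. = FALSE)
    fit <- fcmFit(S, fcmConfig(c = c, m = m, delta = delta,
        maxIter = maxIter, seed = seed))
    Fm <- maxMinCompose(memberships(fit))
    new("FRP", values = Fm, clusters = c, exponent = as.numeric(m))
}

#' Feature vector to fuzzy recurrence plot
#'
#' Composes the per-image transform of the pipeline: FCM compression of
#' the flattened feature vector to \code{n} sorted cluster centers,
#' time-delay embedding, and FRP construction. With the pipeline defaults
#' (\code{n = 13}, \code{d = 1}, \code{tau = 1}, \code{frpC = 3},
#' \code{m = 2}) a 13 x 13 FRP results from any feature vector.
#'
#' @param g numeric flattened feature vector.
#' @param config a \code{\link{pipelineConfig}} list supplying n, d, tau,
#'   frpC, m, delta, maxIter and the stage seeds.
#' @return An \linkS4class{FRP}.
#' @examples
#' frp <- featuresToFRP(rnorm(256), pipelineConfig(seed = 3))
#' dim(frp)
#' @export
featuresToFRP <- function(g, config = pipelineConfig()) {
    seeds <- config$stageSeeds
    x <- compressSequence(g, n = config$n,
        config = fcmConfig(c = config$n, m = config$m, delta = config$delta,
            maxIter = config$maxIter, seed = seeds[["compress"]]),
        order = config$centerOrder)
    S <- embedSequence(x, d = config$d, tau = config$tau)
    buildFRP(S, c = config$frpC, m = config$m, delta = config$delta,
        maxIter = config$maxIter, seed = seeds[["frp"]])
}

#' Image to fuzzy recurrence plot
#'
#' Full per-image transform: read/preprocess the image for the chosen
#' backbone, extract the flattened global-average-pooling features, and
#' convert them to an FRP with \code{\link{featuresToFRP}}. Deterministic
#' given the pipeline seed.
#'
#' @param image image path or array accepted by
#'   \code{\link{preprocessImage}}.
#' @param backbone backbone name or \linkS4class{BackboneSpec}.
#' @param config a \code{\link{pipelineConfig}}.
#' @param model optional instantiated backbone model from
#'   \code{\link{instantiateBackbone}} (reused across images; built on
#'   the fly otherwise).
#' @return An \linkS4class{FRP}.
#' @export
imageToFRP <- function(image, backbone = "resnet101",
                       config = pipelineConfig(), model = NULL) {
    spec <- if (is(backbone, "BackboneSpec")) backbone
        else backboneSpec(backbone)
    if (is.null(model))
        model <- instantiateBackbone(spec,
            seed = config$stageSeeds[["weights"]])
    g <- extractCNNFeatures(image, spec, model = model)
    featuresToFRP(g, config)
}

#' Read and write FRP matrices
#'
#' \code{writeFRP} stores an FRP losslessly as a headerless CSV of its
#' matrix; \code{readFRP} restores it. \code{writeFRPImage} exports the
#' 8-bit grayscale PNG rendering \code{round(255 * F)} — lossy, for
#' visualization only.
#'
#' @param frp an \linkS4class{FRP}.
#' @param path output/input file path.
#' @param clusters,exponent FRP construction parameters recorded on read
#'   (CSV stores only the matrix).
#' @return \code{readFRP} returns an \linkS4class{FRP}; the writers
#'   return \code{path} invisibly.
#' @export
writeFRP <- function(frp, path) {
    stopifnot(is(frp, "FRP"))
    utils::write.table(frp@values, path, sep = ",", row.names = FALSE,
        col.names = FALSE)
    invisible(path)
}

#' @rdname writeFRP
#' @export
readFRP <- function(path, clusters = 3L, exponent = 2) {
    Fm <- as.matrix(utils::read.table(path, sep = ","))
    dimnames(Fm) <- NULL
    ## guard against round-trip noise on the constraints
    Fm <- (Fm + t(Fm)) / 2
    diag(Fm) <- 1
    new("FRP", values = pmin(pmax(Fm, 0), 1), clusters = as.integer(clusters),
        exponent = as.numeric(exponent))
}

#' @rdname writeFRP
#' @export
writeFRPImage <- function(frp, path) {
    stopifnot(is(frp, "FRP"))
    png::writePNG(round(255 * frp@values) / 255, path)
    invisible(path)
}
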