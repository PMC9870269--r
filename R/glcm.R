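#' Convert an RGB array to grayscale
#'
#' ITU-R 601 luminance: 0.299 R + 0.587 G + 0.114 B. Grayscale input is
#' returned unchanged.
#'
#' @param image numeric matrix ([H, W]) or array ([H, W, 3]) in [0, 1],
#'   or a file path readable by \code{\link{preprocessImage}} machinery.
#' @return numeric [H, W] matrix in [0, 1].
#' @export
toGrayscale <- function(image) {
    if (is.character(image) || is(image, "Image"))
        image <- readImageArray(image)
    if (is.matrix(image)) return(image)
    d <- dim(image)
    if (length(d) == 3L && d[3] == 3L)
        return(0.299 * image[, , 1] + 0.587 * image[, , 2] +
            0.114 * image[, , 3])
    if (length(d) == 3L && d[3] == 1L) return(image[, , 1])
    stop("cannot convert input to grayscale", call. = FALSE)
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurrences of quantized gray levels at a fixed pixel
#' offset. Intensities in [0, 1] are binned into \code{nLevels} equal
#' intervals over the full [0, 1] range. Angles follow the usual
#' convention: 0 degrees pairs a pixel with its right neighbour at the
#' given distance, 45/90/135 degrees rotate the offset counterclockwise.
#' In symmetric mode each pair is counted in both orders.
#'
#' @param gray numeric [H, W] matrix in [0, 1].
#' @param nLevels number of gray levels (default 8).
#' @param distance offset distance in pixels (default 1).
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @param symmetric count ordered pairs in both directions (default TRUE).
#' @param normalize divide by the total count (default FALSE: raw integer
#'   counts).
#' @return \code{nLevels} x \code{nLevels} matrix of counts (or
#'   probabilities when normalized).
#' @export
glcmMatrix <- function(gray, nLevels = 8L, distance = 1L, angle = 0,
                       symmetric = TRUE, normalize = FALSE) {
    stopifnot(is.matrix(gray))
    stopIfNotFinite(gray, "grayscale image")
    off <- glcmOffset(angle, distance)
    H <- nrow(gray); W <- ncol(gray)
    if (H <= abs(off[1]) || W <= abs(off[2]))
        stop(sprintf(
            "image (%d x %d) smaller than the offset distance", H, W),
            call. = FALSE)
    L <- pmin(pmax(floor(gray * nLevels) + 1L, 1L), nLevels)
    rows <- seq_len(H); cols <- seq_len(W)
    r1 <- rows[rows + off[1] >= 1L & rows + off[1] <= H]
    c1 <- cols[cols + off[2] >= 1L & cols + off[2] <= W]
    a <- L[r1, c1, drop = FALSE]
    b <- L[r1 + off[1], c1 + off[2], drop = FALSE]
    counts <- matrix(tabulate((a - 1L) * nLevels + b,
        nbins = nLevels * nLevels), nLevels, nLevels, byrow = TRUE)
    if (symmetric) counts <- counts + t(counts)
    if (normalize) counts / sum(counts) else counts
}

glcmOffset <- function(angle, distance) {
    d <- as.integer(distance)
    switch(as.character(angle),
        "0" = c(0L, d),
        "45" = c(-d, d),
        "90" = c(-d, 0L),
        "135" = c(-d, -d),
        stop("angle must be one of 0, 45, 90, 135", call. = FALSE))
}

#' Haralick texture features of a co-occurrence matrix
#'
#' The classical 14-statistic set computed from a normalized GLCM:
#' angular second moment, contrast, correlation, variance (sum of
#' squares), inverse difference moment, sum average, sum variance, sum
#' entropy, entropy, difference variance, difference entropy, the two
#' information measures of correlation, and the maximal correlation
#' coefficient. Natural logarithms are used, with 0 log 0 = 0.
#' Degenerate cases are defined rather than propagated: correlation and
#' the first information measure are 0 when the marginal variance or
#' entropy vanishes, and the maximal correlation coefficient falls back
#' to 0 when its eigenproblem is degenerate (fewer than two occupied
#' levels, or a non-finite eigenvalue).
#'
#' @param P co-occurrence matrix (counts or probabilities; normalized
#'   internally).
#' @return named numeric(14).
#' @export
haralickFeatures <- function(P) {
    P <- as.matrix(P)
    if (sum(P) <= 0) stop("empty co-occurrence matrix", call. = FALSE)
    P <- P / sum(P)
    N <- nrow(P)
    i <- row(P); j <- col(P)
    px <- rowSums(P); py <- colSums(P)
    lev <- seq_len(N)
    mux <- sum(lev * px); muy <- sum(lev * py)
    sigx <- sqrt(sum((lev - mux)^2 * px))
    sigy <- sqrt(sum((lev - muy)^2 * py))
    xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

    ## marginal distributions of i + j and |i - j|
    psum <- vapply(2:(2 * N), function(k) sum(P[i + j == k]), numeric(1))
    ksum <- 2:(2 * N)
    pdiff <- vapply(0:(N - 1), function(k) sum(P[abs(i - j) == k]),
        numeric(1))
    kdiff <- 0:(N - 1)

    f1 <- sum(P^2)
    f2 <- sum(kdiff^2 * pdiff)
    f3 <- if (sigx > 0 && sigy > 0)
        (sum(i * j * P) - mux * muy) / (sigx * sigy) else 0
    f4 <- sum((i - mux)^2 * P)
    f5 <- sum(P / (1 + (i - j)^2))
    f6 <- sum(ksum * psum)
    f7 <- sum((ksum - f6)^2 * psum)
    f8 <- -sum(xlogx(psum))
    f9 <- -sum(xlogx(P))
    f10 <- sum((kdiff - sum(kdiff * pdiff))^2 * pdiff)
    f11 <- -sum(xlogx(pdiff))

    HX <- -sum(xlogx(px)); HY <- -sum(xlogx(py))
    pxy <- outer(px, py)
    HXY1 <- -sum(P[pxy > 0] * log(pxy[pxy > 0]))
    HXY2 <- -sum(xlogx(pxy))
    f12 <- if (max(HX, HY) > 0) (f9 - HXY1) / max(HX, HY) else 0
    f13 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - f9))))
    f14 <- maximalCorrelation(P, px, py)

    out <- c(f1, f2, f3, f4, f5, f6, f7, f8, f9, f10, f11, f12, f13, f14)
    names(out) <- c("asm", "contrast", "correlation", "variance", "idm",
        "sum_average", "sum_variance", "sum_entropy", "entropy",
        "diff_variance", "diff_entropy", "imc1", "imc2", "mcc")
    out
}

## Maximal correlation coefficient: square root of the second-largest
## eigenvalue of Q(i,j) = sum_k P(i,k) P(j,k) / (px(i) py(k)), computed
## on the occupied levels; 0 on degeneracy.
maximalCorrelation <- function(P, px, py) {
    keep <- px > 0 & py > 0
    if (sum(keep) < 2L) return(0)
    Pk <- P[keep, keep, drop = FALSE]
    pxk <- px[keep]; pyk <- py[keep]
    Q <- (Pk / pxk) %*% t(Pk / rep(pyk, each = nrow(Pk)))
    ev <- tryCatch(eigen(Q, only.values = TRUE)$values,
        error = function(e) NULL)
    if (is.null(ev)) return(0)
    ev <- Re(ev[abs(Im(ev)) < 1e-8])
    if (length(ev) < 2L) return(0)
    lam2 <- sort(ev, decreasing = TRUE)[2]
    if (!is.finite(lam2) || lam2 < 0) return(0)
    sqrt(min(lam2, 1))
}

#' GLCM texture features of an image
#'
#' Converts the image to grayscale (ITU-R 601 luminance), computes the
#' symmetric co-occurrence matrix at the given distance for each of the
#' configured angles, derives the 14 Haralick statistics from each, and
#' averages them over angles. The defaults (8 levels, distance 1, angles
#' 0/45/90/135) give the rotation-averaged descriptor commonly used as a
#' classical texture baseline.
#'
#' @param image grayscale matrix, RGB array, EBImage Image or file path.
#' @param nLevels number of quantized gray levels.
#' @param distance pixel offset distance.
#' @param angles offset angles in degrees, subset of 0/45/90/135.
#' @param symmetric symmetric co-occurrence counting (default TRUE).
#' @return named numeric(14) of angle-averaged Haralick features.
#' @examples
#' extractGLCMFeatures(matrix(runif(64), 8))
#' @export
extractGLCMFeatures <- function(image, nLevels = 8L, distance = 1L,
                                angles = c(0, 45, 90, 135),
                                symmetric = TRUE) {
    gray <- toGrayscale(if (is.character(image) || is(image, "Image"))
        readImageArray(image) else image)
    feats <- vapply(angles, function(a)
        haralickFeatures(glcmMatrix(gray, nLevels = nLevels,
            distance = distance, angle = a, symmetric = symmetric)),
        numeric(14L))
    rowMeans(feats)
}
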