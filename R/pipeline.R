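#' Pipeline configuration
#'
#' Collects the parameters of the full image-to-prediction pipeline with
#' the study defaults: compression to \code{n = 13} cluster centers,
#' identity embedding (\code{d = 1}, \code{tau = 1}), FRP construction
#' with \code{frpC = 3} clusters and fuzzy exponent \code{m = 2}, FCM
#' threshold \code{delta = 1e-5} with at most \code{maxIter = 100}
#' iterations, and the bidirectional-LSTM training configuration. A
#' single global \code{seed} fans out deterministically into independent
#' stage seeds (backbone weights, compression, FRP, training, CV folds).
#'
#' @param backbone backbone name (see \code{\link{listBackbones}}).
#' @param n compressed sequence length (FCM cluster count).
#' @param frpC FRP cluster count.
#' @param m fuzzy exponent for both FCM uses.
#' @param d,tau embedding dimension and time delay.
#' @param delta,maxIter FCM convergence threshold and iteration cap.
#' @param centerOrder ordering of the compressed centers
#'   (\code{"sorted"} or \code{"assignment"}).
#' @param train a \code{\link{trainConfig}} for the LSTM stage.
#' @param k,stratified cross-validation folds and stratification flag.
#' @param seed single global seed.
#' @return A named list of class \code{"PipelineConfig"} including a
#'   \code{stageSeeds} vector.
#' @examples
#' cfg <- pipelineConfig(seed = 11)
#' cfg$stageSeeds
#' @export
pipelineConfig <- function(backbone = "resnet101", n = 13L, frpC = 3L,
                           m = 2, d = 1L, tau = 1L, delta = 1e-5,
                           maxIter = 100L,
                           centerOrder = c("sorted", "assignment"),
                           train = trainConfig(), k = 10L,
                           stratified = TRUE, seed = 1L) {
    centerOrder <- match.arg(centerOrder)
    n <- as.integer(n); frpC <- as.integer(frpC)
    d <- as.integer(d); tau <- as.integer(tau)
    if (n - (d - 1L) * tau < 2L)
        stop("embedding parameters leave fewer than 2 states", call. = FALSE)
    if (frpC < 2L || frpC > n - (d - 1L) * tau)
        stop("frpC must be in [2, M]", call. = FALSE)
    seeds <- deriveSeeds(seed, 5L)
    names(seeds) <- c("weights", "compress", "frp", "train", "cv")
    train$seed <- unname(seeds[["train"]])
    structure(list(
        backbone = backbone, n = n, frpC = frpC, m = as.numeric(m),
        d = d, tau = tau, delta = as.numeric(delta),
        maxIter = as.integer(maxIter), centerOrder = centerOrder,
        train = train, k = as.integer(k), stratified = isTRUE(stratified),
        seed = as.integer(seed), stageSeeds = seeds
    ), class = "PipelineConfig")
}
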