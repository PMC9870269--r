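#' Synthetic IHC-like image generator configuration
#'
#' Describes two-class stained-tissue-like textures: DAB-brown blobs on
#' a hematoxylin-blue background, with the class signal carried by blob
#' density (and hence texture granularity), not by color alone, so both
#' a texture baseline and a convolutional feature path can detect it.
#' Defaults emulate the shape of the study cohort: 29 short-survival
#' ("lt5") and 51 long-survival ("gt5") images, a 3:1 density ratio, and
#' mild additive noise.
#'
#' @param nPerClass named integer(2): images per class (names are the
#'   class labels, negative class first).
#' @param imageSize integer(2): height and width in pixels.
#' @param blobDensity named numeric(2): expected blobs per pixel, per
#'   class (must differ between classes — this is the class signal).
#' @param blobRadius numeric(2): min and max blob radius in pixels.
#' @param stainColor RGB triple of the stained blobs (DAB brown).
#' @param backgroundColor RGB triple of the background (hematoxylin
#'   blue).
#' @param noiseSD additive Gaussian pixel noise standard deviation.
#' @param seed generator seed.
#' @return named list of class \code{"SyntheticImageConfig"}.
#' @export
syntheticImageConfig <- function(nPerClass = c(lt5 = 29L, gt5 = 51L),
                                 imageSize = c(128L, 128L),
                                 blobDensity = c(lt5 = 8e-4, gt5 = 2.4e-3),
                                 blobRadius = c(2, 5),
                                 stainColor = c(0.55, 0.35, 0.15),
                                 backgroundColor = c(0.68, 0.68, 0.85),
                                 noiseSD = 0.02, seed = 1L) {
    if (any(nPerClass < 1L) || any(imageSize < 8L))
        stop("nPerClass and imageSize must be positive (images >= 8 px)",
            call. = FALSE)
    if (length(unique(blobDensity)) < 2L)
        stop("blobDensity must differ between classes (it is the class signal)",
            call. = FALSE)
    if (any(blobDensity <= 0) || noiseSD < 0)
        stop("densities must be positive and noiseSD non-negative",
            call. = FALSE)
    structure(list(nPerClass = nPerClass, imageSize = as.integer(imageSize),
        blobDensity = blobDensity, blobRadius = blobRadius,
        stainColor = stainColor, backgroundColor = backgroundColor,
        noiseSD = noiseSD, seed = as.integer(seed)),
        class = "SyntheticImageConfig")
}

#' Generate a two-class synthetic IHC-like image set
#'
#' Draws, per image, a Poisson number of stained blobs at the class
#' density, paints them as soft-edged disks of the stain color over the
#' background, and adds Gaussian pixel noise. Reproducible: the dataset
#' seed fans out into per-image seeds. When \code{dir} is given the
#' images are written as PNG together with a \code{labels.csv}
#' (image_id, class) matching the pipeline's input contract; otherwise
#' the arrays are returned in memory.
#'
#' @param config a \code{\link{syntheticImageConfig}}.
#' @param dir optional output directory (created if missing).
#' @return list with \code{images} (list of [H, W, 3] arrays; omitted
#'   when written to disk), \code{labels} (data.frame with image_id and
#'   class), and \code{dir} when written.
#' @export
generateImages <- function(config = syntheticImageConfig(), dir = NULL) {
    classes <- names(config$nPerClass)
    if (is.null(classes)) classes <- c("lt5", "gt5")
    total <- sum(config$nPerClass)
    seeds <- deriveSeeds(config$seed, total)
    labels <- rep(classes, config$nPerClass)
    ids <- sprintf("img_%03d_%s", seq_len(total), labels)
    H <- config$imageSize[1]; W <- config$imageSize[2]
    toDisk <- !is.null(dir)
    if (toDisk && !dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    images <- if (toDisk) NULL else vector("list", total)
    for (i in seq_len(total)) {
        A <- withSeed(seeds[i],
            renderStainedImage(H, W, config$blobDensity[[labels[i]]],
                config$blobRadius, config$stainColor,
                config$backgroundColor, config$noiseSD))
        if (toDisk)
            png::writePNG(A, file.path(dir, paste0(ids[i], ".png")))
        else images[[i]] <- A
    }
    lab <- data.frame(image_id = ids, class = labels,
        stringsAsFactors = FALSE)
    if (toDisk) {
        utils::write.csv(lab, file.path(dir, "labels.csv"),
            row.names = FALSE)
        list(labels = lab, dir = dir)
    } else list(images = images, labels = lab)
}

## One H x W x 3 image: background + soft-edged stained disks + noise.
renderStainedImage <- function(H, W, density, radiusRange, stain, bg,
                               noiseSD) {
    nBlobs <- stats::rpois(1, density * H * W)
    A <- array(rep(bg, each = H * W), c(H, W, 3))
    if (nBlobs > 0) {
        cy <- stats::runif(nBlobs, 1, H)
        cx <- stats::runif(nBlobs, 1, W)
        rr <- stats::runif(nBlobs, radiusRange[1], radiusRange[2])
        rows <- matrix(seq_len(H), H, W)
        cols <- matrix(seq_len(W), H, W, byrow = TRUE)
        alpha <- matrix(0, H, W)
        for (b in seq_len(nBlobs)) {
            d2 <- (rows - cy[b])^2 + (cols - cx[b])^2
            ## soft edge over ~1 px at the rim
            a <- pmin(pmax((rr[b] - sqrt(d2)) + 0.5, 0), 1)
            alpha <- pmax(alpha, a)
        }
        for (ch in 1:3)
            A[, , ch] <- A[, , ch] * (1 - alpha) + stain[ch] * alpha
    }
    A <- A + stats::rnorm(length(A), sd = noiseSD)
    pmin(pmax(A, 0), 1)
}

#' Synthetic feature-vector generator configuration
#'
#' Class-structured flattened feature vectors emulating the deep-feature
#' contract: length-N Gaussian vectors with a class mean shift of
#' \code{effectSize} (in within-class standard deviation units) applied
#' to a fixed random subset of \code{shiftFraction} of the coordinates,
#' and within-image correlation between coordinates induced by a shared
#' latent factor of weight \code{rho}.
#'
#' @param nPerClass named integer(2): examples per class.
#' @param N feature length (>= 13 so the vectors stay compressible to
#'   the default 13 cluster centers; default 2048, the ResNet-101
#'   contract).
#' @param effectSize class mean shift in sd units (>= 0; 0 is the null).
#' @param shiftFraction fraction of coordinates carrying the shift.
#' @param rho within-image between-coordinate correlation in [0, 1).
#' @param seed generator seed.
#' @return named list of class \code{"SyntheticFeatureConfig"}.
#' @export
syntheticFeatureConfig <- function(nPerClass = c(lt5 = 29L, gt5 = 51L),
                                   N = 2048L, effectSize = 2,
                                   shiftFraction = 0.25, rho = 0.2,
                                   seed = 1L) {
    if (N < 13L) stop("N must be >= 13", call. = FALSE)
    if (!is.finite(effectSize) || effectSize < 0)
        stop("effectSize must be a finite number >= 0", call. = FALSE)
    if (rho < 0 || rho >= 1)
        stop("rho must be in [0, 1)", call. = FALSE)
    if (shiftFraction <= 0 || shiftFraction > 1)
        stop("shiftFraction must be in (0, 1]", call. = FALSE)
    structure(list(nPerClass = nPerClass, N = as.integer(N),
        effectSize = effectSize, shiftFraction = shiftFraction,
        rho = rho, seed = as.integer(seed)),
        class = "SyntheticFeatureConfig")
}

#' Generate two-class structured feature vectors
#'
#' @param config a \code{\link{syntheticFeatureConfig}}.
#' @return list with \code{features} (matrix, examples x N),
#'   \code{labels} (character), and \code{shiftIndex} (the shifted
#'   coordinate subset).
#' @examples
#' d <- generateFeatures(syntheticFeatureConfig(
#'     nPerClass = c(lt5 = 5, gt5 = 5), N = 64, seed = 2))
#' dim(d$features)
#' @export
generateFeatures <- function(config = syntheticFeatureConfig()) {
    classes <- names(config$nPerClass)
    if (is.null(classes)) classes <- c("lt5", "gt5")
    total <- sum(config$nPerClass)
    labels <- rep(classes, config$nPerClass)
    N <- config$N
    withSeed(config$seed, {
        shiftIdx <- sample.int(N, max(1L, round(config$shiftFraction * N)))
        X <- matrix(0, total, N)
        for (i in seq_len(total)) {
            z <- stats::rnorm(1)
            g <- sqrt(config$rho) * z +
                sqrt(1 - config$rho) * stats::rnorm(N)
            if (labels[i] == classes[2])
                g[shiftIdx] <- g[shiftIdx] + config$effectSize
            X[i, ] <- g
        }
        list(features = X, labels = labels, shiftIndex = sort(shiftIdx))
    })
}

#' Cross-validated FRP-LSTM pipeline over feature vectors
#'
#' Converts each flattened feature vector to a fuzzy recurrence plot
#' with the configured compression, embedding and FRP parameters, then
#' cross-validates the bidirectional-LSTM classifier over the FRPs.
#' This is the end-to-end path from deep features to the performance
#' report, with every stage seeded from the pipeline seed.
#'
#' @param features numeric matrix, one flattened feature vector per row.
#' @param labels two-class labels.
#' @param config a \code{\link{pipelineConfig}}.
#' @param positive positive-class label (default \code{"gt5"} when
#'   present).
#' @return A \linkS4class{MetricsReport}.
#' @export
frpPipelineCV <- function(features, labels, config = pipelineConfig(),
                          positive = NULL) {
    features <- as.matrix(features)
    frps <- lapply(seq_len(nrow(features)), function(i)
        featuresToFRP(features[i, ], config))
    runCVExperiment(frps, labels, lstmModelSpec(config$train,
        positive = positive), k = config$k,
        stratified = config$stratified,
        seed = config$stageSeeds[["cv"]], positive = positive)
}
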