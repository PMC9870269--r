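## Backbone registry. Each entry maps a backbone name to its canonical
## input size, the role-defined extraction point (the final global
## average pooling before the fully-connected head), the historical
## layer-name aliases, and a layer-graph builder where a numerical
## forward pass is provided.

.backboneRegistry <- list(
    resnet101 = list(
        inputSize = c(224L, 224L),
        extractionLayer = "pool5",
        aliases = c("pool5", "gap", "global_average_pooling"),
        builder = function() buildResNet101(),
        normalization = "imagenet"
    ),
    densenet201 = list(
        inputSize = c(224L, 224L),
        extractionLayer = "avg_pool",
        aliases = c("avg_pool", "gap", "global_average_pooling"),
        builder = function() buildDenseNet201(),
        normalization = "imagenet"
    ),
    nasnetlarge = list(
        inputSize = c(331L, 331L),
        extractionLayer = "global_average_pooling2d_2",
        aliases = c("global_average_pooling2d_2", "gap",
            "global_average_pooling"),
        builder = NULL,                # shape rule only, no forward pass
        normalization = "pm1"
    )
)

.graphCache <- new.env(parent = emptyenv())

backboneGraph <- function(name) {
    if (is.null(.backboneRegistry[[name]]$builder)) return(NULL)
    if (is.null(.graphCache[[name]]))
        .graphCache[[name]] <- .backboneRegistry[[name]]$builder()
    .graphCache[[name]]
}

#' List registered backbones
#'
#' @return character vector of backbone names.
#' @examples listBackbones()
#' @export
listBackbones <- function() names(.backboneRegistry)

#' Backbone specification
#'
#' Looks up a backbone by name and returns its specification. The
#' flattened feature length is derived from the architecture itself:
#' for ResNet-101 and DenseNet-201 by shape inference over the full
#' in-package layer graph at the canonical input size; for NASNet-Large
#' from its cell-stacking rule (6 concatenated branches, 168 base
#' filters, two filter-doubling reductions).
#'
#' @param name one of \code{"resnet101"}, \code{"densenet201"},
#'   \code{"nasnetlarge"}.
#' @return A \linkS4class{BackboneSpec}.
#' @examples
#' backboneSpec("resnet101")
#' @export
backboneSpec <- function(name = listBackbones()) {
    name <- match.arg(name)
    entry <- .backboneRegistry[[name]]
    fl <- if (!is.null(entry$builder)) {
        g <- backboneGraph(name)
        shapes <- graphShapes(g, c(entry$inputSize, 3L))
        utils::tail(shapes, 1)[[1]][3]
    } else nasnetLargeFeatureLength()
    new("BackboneSpec", name = name,
        inputSize = entry$inputSize,
        extractionLayer = entry$extractionLayer,
        featureLength = as.integer(fl),
        forwardAvailable = !is.null(entry$builder))
}

#' Flattened feature length of a backbone
#'
#' @param spec backbone name or \linkS4class{BackboneSpec}.
#' @return integer(1): length of the flattened global-average-pooling
#'   activation (2048 for ResNet-101, 1920 for DenseNet-201, 4032 for
#'   NASNet-Large).
#' @examples featureLength("densenet201")
#' @export
featureLength <- function(spec) {
    if (is.character(spec)) spec <- backboneSpec(spec)
    spec@featureLength
}

#' Instantiate a backbone with seeded random weights
#'
#' Builds the backbone's layer graph and draws seeded He-normal weights
#' for every convolution plus near-identity channelwise affines. No
#' pretrained weights ship with the package: the instantiated model
#' yields architecture-faithful feature dimensions and a deterministic,
#' content-dependent feature map, which is what the pipeline's shape and
#' plumbing contracts require. A hook for loading externally obtained
#' weights can be layered on the same graph structure.
#'
#' @param spec backbone name or \linkS4class{BackboneSpec} (must have a
#'   forward pass available).
#' @param seed weight-initialization seed.
#' @param weights optional externally obtained weights: a named list
#'   whose entries replace the seeded-random parameters of the matching
#'   graph nodes (conv nodes take \code{W}/\code{b}, affine nodes
#'   \code{scale}/\code{shift}); shapes are checked. This is the hook
#'   for loading pretrained or fine-tuned parameters.
#' @return list with the spec, graph and weights, class
#'   \code{"BackboneModel"}.
#' @export
instantiateBackbone <- function(spec = "resnet101", seed = 1L,
                                weights = NULL) {
    if (is.character(spec)) spec <- backboneSpec(spec)
    if (!spec@forwardAvailable)
        stop(sprintf(
            "backbone '%s' is registered for shape inference only; no forward pass is available",
            spec@name), call. = FALSE)
    g <- backboneGraph(spec@name)
    w <- graphWeights(g, c(spec@inputSize, 3L), seed)
    if (!is.null(weights)) {
        for (nm in names(weights)) {
            if (is.null(w[[nm]]))
                stop(sprintf("'%s' is not a parameterized node of '%s'",
                    nm, spec@name), call. = FALSE)
            for (pn in names(weights[[nm]])) {
                tgt <- w[[nm]][[pn]]
                if (is.null(tgt) ||
                    !identical(dim(tgt) %||% length(tgt),
                        dim(weights[[nm]][[pn]]) %||%
                            length(weights[[nm]][[pn]])))
                    stop(sprintf("shape mismatch for %s$%s", nm, pn),
                        call. = FALSE)
                w[[nm]][[pn]] <- weights[[nm]][[pn]]
            }
        }
    }
    structure(list(spec = spec, graph = g, weights = w, seed = seed),
        class = "BackboneModel")
}

## canonical ImageNet channel statistics used by the 224x224 backbones
.imagenetMean <- c(0.485, 0.456, 0.406)
.imagenetSD <- c(0.229, 0.224, 0.225)

#' Read and preprocess an image for a backbone
#'
#' Reads PNG/TIFF/JPEG (via EBImage) or accepts an in-memory array,
#' converts grayscale to RGB by channel replication, resizes with
#' bilinear interpolation to the backbone's canonical input size, and
#' applies the backbone's training-time channel normalization (ImageNet
#' mean/sd for the 224x224 backbones, [-1, 1] scaling for NASNet-Large).
#' Deterministic: no augmentation of any kind.
#'
#' @param image file path, EBImage \code{Image}, or numeric array
#'   ([H, W, 3] or [H, W]) with values in [0, 1].
#' @param spec backbone name or \linkS4class{BackboneSpec}.
#' @return numeric array [H, W, 3] at the backbone input size.
#' @export
preprocessImage <- function(image, spec = "resnet101") {
    if (is.character(spec)) spec <- backboneSpec(spec)
    A <- readImageArray(image)
    tgt <- spec@inputSize
    if (!identical(dim(A)[1:2], tgt)) {
        img <- EBImage::Image(aperm(A, c(2, 1, 3)), colormode = "Color")
        img <- EBImage::resize(img, w = tgt[2], h = tgt[1],
            filter = "bilinear")
        A <- aperm(EBImage::imageData(img), c(2, 1, 3))
    }
    A <- pmin(pmax(A, 0), 1)
    norm <- .backboneRegistry[[spec@name]]$normalization
    if (identical(norm, "imagenet")) {
        plane <- prod(dim(A)[1:2])
        A <- (A - rep(.imagenetMean, each = plane)) /
            rep(.imagenetSD, each = plane)
    } else {
        A <- 2 * A - 1
    }
    A
}

## Accept a path, EBImage Image or plain array; return [H, W, 3] in [0, 1].
readImageArray <- function(image) {
    if (is.character(image)) {
        if (!file.exists(image))
            stop(sprintf("image file '%s' not found", image), call. = FALSE)
        image <- EBImage::readImage(image)
    }
    if (is(image, "Image")) {
        A <- EBImage::imageData(image)
        if (length(dim(A)) == 2L) A <- array(A, c(dim(A), 1L))
        if (dim(A)[3] > 3L) A <- A[, , 1:3, drop = FALSE]   # drop alpha
        A <- aperm(A, c(2, 1, 3))
    } else if (is.array(image) || is.matrix(image)) {
        A <- image
        if (length(dim(A)) == 2L) A <- array(A, c(dim(A), 1L))
        if (dim(A)[3] > 3L) A <- A[, , 1:3, drop = FALSE]
    } else {
        stop("unsupported image input; give a file path or an array",
            call. = FALSE)
    }
    storage.mode(A) <- "double"
    if (any(!is.finite(A)))
        stop("image contains non-finite values", call. = FALSE)
    if (dim(A)[3] == 1L) A <- array(rep(A, 3L), c(dim(A)[1:2], 3L))
    if (dim(A)[3] == 2L)
        stop("cannot interpret a 2-channel image as RGB", call. = FALSE)
    A
}

#' Extract flattened deep features at the global-average-pooling layer
#'
#' Preprocesses the image for the backbone and runs the in-package
#' forward pass, returning the flattened activation of the final global
#' average pooling layer. The length of the result depends only on the
#' architecture, never on image content or the particular weights.
#'
#' @param image image path or array (see \code{\link{preprocessImage}}).
#' @param spec backbone name or \linkS4class{BackboneSpec}.
#' @param model instantiated model from \code{\link{instantiateBackbone}};
#'   built with \code{seed} if omitted.
#' @param seed weight seed used when \code{model} is NULL.
#' @param layer optional extraction-layer name; the role-defined global
#'   average pooling is always used, and this argument only checks the
#'   requested name against the backbone's known aliases, erroring with
#'   the candidates otherwise.
#' @return numeric feature vector of length \code{featureLength(spec)},
#'   with attributes \code{backbone} and \code{layer}.
#' @export
extractCNNFeatures <- function(image, spec = "resnet101", model = NULL,
                               seed = 1L, layer = NULL) {
    if (is.character(spec)) spec <- backboneSpec(spec)
    entry <- .backboneRegistry[[spec@name]]
    if (!is.null(layer) && !(layer %in% entry$aliases))
        stop(sprintf(
            "layer '%s' not found in backbone '%s'; candidates: %s",
            layer, spec@name, paste(entry$aliases, collapse = ", ")),
            call. = FALSE)
    if (is.null(model)) model <- instantiateBackbone(spec, seed = seed)
    if (!identical(model$spec@name, spec@name))
        stop("model was instantiated for a different backbone",
            call. = FALSE)
    A <- preprocessImage(image, spec)
    out <- forwardGraph(model$graph, model$weights, A)
    g <- as.numeric(out)
    attr(g, "backbone") <- spec@name
    attr(g, "layer") <- spec@extractionLayer
    g
}

#' Feature cache I/O
#'
#' \code{writeFeatureCache} writes one row per image (image_id, backbone,
#' then the feature values) to CSV; \code{readFeatureCache} restores a
#' list with the feature matrix and metadata.
#'
#' @param features numeric matrix (images x feature length) or list of
#'   equal-length vectors.
#' @param imageIds character vector of image identifiers.
#' @param backbone backbone name tag.
#' @param path CSV path.
#' @return \code{readFeatureCache} returns a list with elements
#'   \code{features} (matrix), \code{imageIds}, \code{backbone}.
#' @export
writeFeatureCache <- function(features, imageIds, backbone, path) {
    if (is.list(features)) features <- do.call(rbind, features)
    df <- data.frame(image_id = imageIds, backbone = backbone,
        features, check.names = FALSE)
    names(df)[-(1:2)] <- paste0("f", seq_len(ncol(features)))
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeFeatureCache
#' @export
readFeatureCache <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    M <- as.matrix(df[, -(1:2), drop = FALSE])
    dimnames(M) <- NULL
    list(features = M, imageIds = as.character(df$image_id),
        backbone = unique(as.character(df$backbone)))
}
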