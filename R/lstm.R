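#' LSTM training configuration
#'
#' Defaults follow the study protocol: at most 300 epochs, batch size
#' 150 (clamped to the training-set size, i.e. full-batch on small
#' cohorts), initial learning rate 0.01, gradient threshold 1 (global
#' L2-norm clipping), bidirectional layer with hidden size 100. Training
#' additionally stops early once the cross-entropy falls below
#' \code{lossTol}, which never changes the fitted decision on separable
#' data but avoids idle epochs.
#'
#' @param maxEpochs maximum number of epochs.
#' @param batchSize minibatch size (clamped to the number of examples).
#' @param learningRate Adam step size.
#' @param gradientThreshold global L2-norm clipping threshold.
#' @param bidirectional process the sequence in both directions.
#' @param hiddenSize hidden state width per direction.
#' @param lossTol early-stop threshold on the training cross-entropy.
#' @param seed seed for weight initialization and epoch shuffling.
#' @return named list of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(maxEpochs = 300L, batchSize = 150L,
                        learningRate = 0.01, gradientThreshold = 1,
                        bidirectional = TRUE, hiddenSize = 100L,
                        lossTol = 1e-3, seed = 1L) {
    stopifnot(maxEpochs >= 1L, batchSize >= 1L, learningRate > 0,
        gradientThreshold > 0, hiddenSize >= 1L)
    structure(list(maxEpochs = as.integer(maxEpochs),
        batchSize = as.integer(batchSize),
        learningRate = learningRate,
        gradientThreshold = gradientThreshold,
        bidirectional = isTRUE(bidirectional),
        hiddenSize = as.integer(hiddenSize),
        lossTol = lossTol, seed = as.integer(seed)),
        class = "TrainConfig")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Reference LSTM cell step
#'
#' Direct per-gate evaluation of one LSTM time step: input, forget and
#' output gates through the logistic sigmoid, cell candidate and state
#' activation through the hyperbolic tangent, cell state
#' \eqn{c_t = f_t \circ c_{t-1} + u_t \circ w_t} and hidden state
#' \eqn{h_t = e_t \circ \tanh(c_t)} with Hadamard products. This is the
#' verification reference the batched training layer is checked against.
#'
#' @param weights list with elements \code{I} (input weights: list
#'   \code{u}, \code{f}, \code{w}, \code{e}, each hidden x input),
#'   \code{R} (recurrent weights: same names, hidden x hidden) and
#'   \code{b} (biases: same names, length hidden).
#' @param z input feature vector at this time step.
#' @param prev list with hidden state \code{h} and cell state \code{c}
#'   from the previous step.
#' @return list with the new \code{h} and \code{c}, plus the gate values
#'   \code{u}, \code{f}, \code{w}, \code{e}.
#' @examples
#' w <- list(I = list(u = matrix(1), f = matrix(1), w = matrix(1),
#'         e = matrix(1)),
#'     R = list(u = matrix(0), f = matrix(0), w = matrix(0),
#'         e = matrix(0)),
#'     b = list(u = 0, f = 0, w = 0, e = 0))
#' lstmCellStep(w, z = 0, prev = list(h = 0, c = 1))
#' @export
lstmCellStep <- function(weights, z, prev) {
    z <- as.numeric(z)
    h <- as.numeric(prev$h); cc <- as.numeric(prev$c)
    gate <- function(part) {
        Iw <- as.matrix(weights$I[[part]])
        Rw <- as.matrix(weights$R[[part]])
        if (ncol(Iw) != length(z) || ncol(Rw) != length(h) ||
            nrow(Iw) != length(h))
            stop("LSTM cell weight dimensions are inconsistent",
                call. = FALSE)
        drop(Iw %*% z + Rw %*% h + as.numeric(weights$b[[part]]))
    }
    u <- sigmoid(gate("u"))
    f <- sigmoid(gate("f"))
    w <- tanh(gate("w"))
    e <- sigmoid(gate("e"))
    cNew <- f * cc + u * w
    hNew <- e * tanh(cNew)
    list(h = hNew, c = cNew, u = u, f = f, w = w, e = e)
}

## Stacked weight layout used by the batched layer: rows are the four
## gate blocks in order u, f, w, e.
lstmInitWeights <- function(inputSize, hiddenSize, outClasses, seed,
                            bidirectional = TRUE) {
    withSeed(seed, {
        H <- hiddenSize; D <- inputSize
        mk <- function() list(
            Wi = matrix(stats::rnorm(4 * H * D, sd = 1 / sqrt(D)),
                4 * H, D),
            Wr = matrix(stats::rnorm(4 * H * H, sd = 1 / sqrt(H)),
                4 * H, H),
            b = { b <- numeric(4 * H); b[(H + 1):(2 * H)] <- 1; b })
        dirs <- list(fwd = mk())
        if (bidirectional) dirs$bwd <- mk()
        outIn <- H * length(dirs)
        dirs$head <- list(
            W = matrix(stats::rnorm(outClasses * outIn,
                sd = 1 / sqrt(outIn)), outClasses, outIn),
            b = numeric(outClasses))
        dirs
    })
}

## Convert a stacked direction weight set into the per-gate list form
## consumed by lstmCellStep.
cellWeightsFromLayer <- function(dir, hiddenSize) {
    H <- hiddenSize
    blk <- function(M, k) M[((k - 1) * H + 1):(k * H), , drop = FALSE]
    vblk <- function(v, k) v[((k - 1) * H + 1):(k * H)]
    list(
        I = list(u = blk(dir$Wi, 1), f = blk(dir$Wi, 2),
            w = blk(dir$Wi, 3), e = blk(dir$Wi, 4)),
        R = list(u = blk(dir$Wr, 1), f = blk(dir$Wr, 2),
            w = blk(dir$Wr, 3), e = blk(dir$Wr, 4)),
        b = list(u = vblk(dir$b, 1), f = vblk(dir$b, 2),
            w = vblk(dir$b, 3), e = vblk(dir$b, 4)))
}

## Batched forward over one direction. X: [B, T, D]. Returns the final
## hidden state and, when keep = TRUE, the per-step caches for BPTT.
lstmDirectionForward <- function(dir, X, hiddenSize, reverse = FALSE,
                                 keep = FALSE) {
    B <- dim(X)[1]; Tn <- dim(X)[2]
    H <- hiddenSize
    idx <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
    h <- matrix(0, B, H); cc <- matrix(0, B, H)
    cache <- if (keep) vector("list", Tn) else NULL
    gi <- list(u = 1:H, f = (H + 1):(2 * H), w = (2 * H + 1):(3 * H),
        e = (3 * H + 1):(4 * H))
    for (s in seq_len(Tn)) {
        Z <- X[, idx[s], , drop = FALSE]
        dim(Z) <- c(B, dim(X)[3])
        A <- Z %*% t(dir$Wi) + h %*% t(dir$Wr) +
            matrix(dir$b, B, 4 * H, byrow = TRUE)
        u <- sigmoid(A[, gi$u, drop = FALSE])
        f <- sigmoid(A[, gi$f, drop = FALSE])
        w <- tanh(A[, gi$w, drop = FALSE])
        e <- sigmoid(A[, gi$e, drop = FALSE])
        cPrev <- cc
        cc <- f * cPrev + u * w
        tc <- tanh(cc)
        hPrev <- h
        h <- e * tc
        if (keep)
            cache[[s]] <- list(Z = Z, u = u, f = f, w = w, e = e,
                cPrev = cPrev, hPrev = hPrev, c = cc, tc = tc)
    }
    list(h = h, cache = cache, idx = idx)
}

## BPTT through one direction given the gradient at its final hidden
## state. Returns parameter gradients.
lstmDirectionBackward <- function(dir, fwd, dhFinal, hiddenSize) {
    H <- hiddenSize
    Tn <- length(fwd$cache)
    dWi <- matrix(0, nrow(dir$Wi), ncol(dir$Wi))
    dWr <- matrix(0, nrow(dir$Wr), ncol(dir$Wr))
    db <- numeric(length(dir$b))
    dh <- dhFinal
    dc <- matrix(0, nrow(dhFinal), H)
    for (s in rev(seq_len(Tn))) {
        cs <- fwd$cache[[s]]
        dcTot <- dc + dh * cs$e * (1 - cs$tc^2)
        de <- dh * cs$tc
        du <- dcTot * cs$w
        dw <- dcTot * cs$u
        df <- dcTot * cs$cPrev
        dA <- cbind(du * cs$u * (1 - cs$u),
                    df * cs$f * (1 - cs$f),
                    dw * (1 - cs$w^2),
                    de * cs$e * (1 - cs$e))
        dWi <- dWi + t(dA) %*% cs$Z
        dWr <- dWr + t(dA) %*% cs$hPrev
        db <- db + colSums(dA)
        dh <- dA %*% dir$Wr
        dc <- dcTot * cs$f
    }
    list(Wi = dWi, Wr = dWr, b = db)
}

softmaxRows <- function(S) {
    S <- S - apply(S, 1, max)
    E <- exp(S)
    E / rowSums(E)
}

## Forward through the whole classifier. X: [B, T, D]. Returns scores and
## caches.
classifierForward <- function(wts, X, config, keep = FALSE) {
    H <- config$hiddenSize
    fwd <- lstmDirectionForward(wts$fwd, X, H, reverse = FALSE,
        keep = keep)
    feats <- fwd$h
    bwd <- NULL
    if (!is.null(wts$bwd)) {
        bwd <- lstmDirectionForward(wts$bwd, X, H, reverse = TRUE,
            keep = keep)
        feats <- cbind(feats, bwd$h)
    }
    S <- feats %*% t(wts$head$W) +
        matrix(wts$head$b, nrow(feats), length(wts$head$b), byrow = TRUE)
    list(scores = softmaxRows(S), feats = feats, fwd = fwd, bwd = bwd)
}

flattenGrads <- function(gr) unlist(gr, use.names = FALSE)

#' Train a bidirectional LSTM classifier on fuzzy recurrence plots
#'
#' Treats each M x M FRP as a sequence of M time steps with M features
#' per step (rows are time steps), runs it through a (by default)
#' bidirectional LSTM layer, concatenates the two final hidden states,
#' and maps them through a fully-connected layer with softmax to two
#' class scores. Training minimizes the cross-entropy with Adam at the
#' configured learning rate, clipping the global gradient L2 norm at the
#' configured threshold; the batch size is clamped to the number of
#' training examples. Fully seeded and reproducible on a fixed platform.
#'
#' @param frps list of \linkS4class{FRP} objects or square numeric
#'   matrices sharing the same size M.
#' @param labels vector of two class labels, one per FRP.
#' @param config a \code{\link{trainConfig}}.
#' @param positive label of the positive class. Defaults to
#'   \code{"gt5"} when present among the labels, otherwise the second
#'   factor level.
#' @return A \linkS4class{BiLSTMClassifier}.
#' @seealso \code{\link{predictLSTM}}, \code{\link{lstmCellStep}}
#' @export
trainLSTM <- function(frps, labels, config = trainConfig(),
                      positive = NULL) {
    X <- frpBatch(frps)
    B <- dim(X)[1]; Tn <- dim(X)[2]
    labels <- as.character(labels)
    if (length(labels) != B)
        stop("one label per FRP required", call. = FALSE)
    lev <- classLevelsFor(labels, positive)
    if (length(unique(labels)) < 2L)
        stop("training set must contain both classes", call. = FALSE)
    y <- match(labels, lev)            # 1 = negative, 2 = positive
    Y <- matrix(0, B, 2L); Y[cbind(seq_len(B), y)] <- 1

    wts <- lstmInitWeights(dim(X)[3], config$hiddenSize, 2L, config$seed,
        config$bidirectional)
    batch <- min(config$batchSize, B)
    adam <- list(m = NULL, v = NULL, t = 0)
    log <- vector("list", config$maxEpochs)
    shufSeeds <- deriveSeeds(config$seed + 1L, config$maxEpochs)

    for (epoch in seq_len(config$maxEpochs)) {
        ord <- if (batch < B)
            withSeed(shufSeeds[epoch], sample.int(B)) else seq_len(B)
        lossSum <- 0; correct <- 0
        for (start in seq(1L, B, by = batch)) {
            take <- ord[start:min(start + batch - 1L, B)]
            Xb <- X[take, , , drop = FALSE]
            Yb <- Y[take, , drop = FALSE]
            fw <- classifierForward(wts, Xb, config, keep = TRUE)
            P <- fw$scores
            lossSum <- lossSum - sum(log(pmax(P[Yb == 1], 1e-12)))
            correct <- correct + sum(max.col(P) == max.col(Yb))
            grads <- classifierBackward(wts, fw, Xb, Yb, P, config)
            wts <- adamStep(wts, grads, adam, config)
            adam <- attr(wts, "adam")
        }
        log[[epoch]] <- c(epoch = epoch, loss = lossSum / B,
            accuracy = correct / B)
        if (lossSum / B < config$lossTol) break
    }
    log <- as.data.frame(do.call(rbind, log[!vapply(log, is.null,
        logical(1))]))
    new("BiLSTMClassifier", weights = wts, config = unclass(config),
        classLevels = lev, M = as.integer(Tn), trainLog = log)
}

classLevelsFor <- function(labels, positive) {
    lev <- levels(factor(labels))
    if (length(lev) < 2L)
        stop("training set must contain both classes", call. = FALSE)
    if (length(lev) > 2L)
        stop("exactly two classes required", call. = FALSE)
    if (is.null(positive)) positive <- if ("gt5" %in% lev) "gt5" else lev[2]
    if (!positive %in% lev)
        stop(sprintf("positive class '%s' not among the labels", positive),
            call. = FALSE)
    c(setdiff(lev, positive), positive)
}

classifierBackward <- function(wts, fw, Xb, Yb, P, config) {
    H <- config$hiddenSize
    Bn <- nrow(Yb)
    dS <- (P - Yb) / Bn
    grads <- list(
        head = list(W = t(dS) %*% fw$feats, b = colSums(dS)))
    dFeats <- dS %*% wts$head$W
    grads$fwd <- lstmDirectionBackward(wts$fwd, fw$fwd,
        dFeats[, 1:H, drop = FALSE], H)
    if (!is.null(wts$bwd))
        grads$bwd <- lstmDirectionBackward(wts$bwd, fw$bwd,
            dFeats[, (H + 1):(2 * H), drop = FALSE], H)
    grads
}

adamStep <- function(wts, grads, adam, config) {
    gvec <- flattenGrads(grads)
    nrm <- sqrt(sum(gvec^2))
    scale <- if (nrm > config$gradientThreshold)
        config$gradientThreshold / nrm else 1
    gvec <- gvec * scale
    if (is.null(adam$m)) {
        adam$m <- numeric(length(gvec))
        adam$v <- numeric(length(gvec))
    }
    adam$t <- adam$t + 1
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    adam$m <- b1 * adam$m + (1 - b1) * gvec
    adam$v <- b2 * adam$v + (1 - b2) * gvec^2
    mh <- adam$m / (1 - b1^adam$t)
    vh <- adam$v / (1 - b2^adam$t)
    step <- config$learningRate * mh / (sqrt(vh) + eps)

    ## walk the weight tree in the same order as flattenGrads
    pos <- 0L
    assign1 <- function(w, g) {
        n <- length(w)
        out <- w - array(step[(pos + 1L):(pos + n)], dim = dim(w) %||%
            length(w))
        pos <<- pos + n
        out
    }
    for (nm in names(grads)) {
        for (pn in names(grads[[nm]]))
            wts[[nm]][[pn]] <- assign1(wts[[nm]][[pn]], grads[[nm]][[pn]])
    }
    attr(wts, "adam") <- adam
    wts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

frpBatch <- function(frps) {
    mats <- lapply(frps, function(f)
        if (is(f, "FRP")) frpMatrix(f) else as.matrix(f))
    Ms <- vapply(mats, nrow, numeric(1))
    if (length(unique(Ms)) != 1L ||
        any(vapply(mats, ncol, numeric(1)) != Ms[1]))
        stop("all FRPs must be square matrices of the same size",
            call. = FALSE)
    M <- Ms[1]
    X <- array(0, c(length(mats), M, M))
    for (i in seq_along(mats)) X[i, , ] <- mats[[i]]   # rows = time steps
    X
}

#' Predict survival classes from FRPs
#'
#' Runs the trained classifier on a batch of FRPs and returns per-example
#' softmax scores (summing to 1) and hard labels. An exact 0.5/0.5 tie is
#' resolved to the positive class. Predictions are independent across
#' examples, so any batching of the same inputs yields identical results.
#'
#' @param model a trained \linkS4class{BiLSTMClassifier}.
#' @param frps list of \linkS4class{FRP} objects or matrices with the
#'   size the model was trained on.
#' @return list with \code{scores} (matrix, columns named by class) and
#'   \code{labels} (character vector).
#' @export
predictLSTM <- function(model, frps) {
    stopifnot(is(model, "BiLSTMClassifier"))
    X <- frpBatch(frps)
    if (dim(X)[2] != model@M)
        stop(sprintf("FRP size %d does not match the trained size %d",
            dim(X)[2], model@M), call. = FALSE)
    cfg <- model@config
    P <- classifierForward(model@weights, X, cfg)$scores
    colnames(P) <- model@classLevels
    labels <- ifelse(P[, 2] >= P[, 1], model@classLevels[2],
        model@classLevels[1])
    list(scores = P, labels = labels)
}

#' Linear SVM baseline
#'
#' Trains a standardized linear-kernel support vector machine on
#' flattened feature vectors (deep or GLCM), as the classical baseline
#' against the FRP-LSTM path. Thin wrapper over \code{e1071::svm}.
#'
#' @param features numeric matrix, one row per example.
#' @param labels two-class label vector.
#' @param positive positive-class label (same convention as
#'   \code{\link{trainLSTM}}).
#' @param cost SVM cost parameter.
#' @return list with the fitted \code{svm} object and the class levels,
#'   class \code{"LinearSVM"}.
#' @export
trainSVM <- function(features, labels, positive = NULL, cost = 1) {
    features <- as.matrix(features)
    labels <- as.character(labels)
    lev <- classLevelsFor(labels, positive)
    if (length(unique(labels)) < 2L)
        stop("training set must contain both classes", call. = FALSE)
    fit <- e1071::svm(features, factor(labels, levels = lev),
        kernel = "linear", scale = apply(features, 2, stats::sd) > 0,
        cost = cost)
    structure(list(fit = fit, classLevels = lev), class = "LinearSVM")
}

#' @rdname trainSVM
#' @param model a fitted \code{"LinearSVM"}.
#' @param newdata numeric matrix of examples to classify.
#' @export
predictSVM <- function(model, newdata) {
    as.character(stats::predict(model$fit, as.matrix(newdata)))
}
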