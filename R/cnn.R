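## Minimal convolutional-network engine.
##
## Backbone architectures are declared as flat layer graphs (topologically
## ordered node lists) and executed with an im2col + BLAS GEMM forward
## pass. Activations are [H, W, C] arrays. Only the operations the
## registered backbones need are implemented: conv, channelwise affine
## (the inference-time form of batch normalization), relu, max/average
## pooling, global average pooling, residual add and channel concat.

newGraph <- function() {
    env <- new.env(parent = emptyenv())
    env$nodes <- list()
    env
}

addNode <- function(g, id, op, inputs = character(), ...) {
    g$nodes[[id]] <- list(id = id, op = op, inputs = inputs,
        params = list(...))
    id
}

## ---- shape inference ------------------------------------------------------

convOutDim <- function(size, k, s, p) (size + 2L * p - k) %/% s + 1L

#' @noRd
graphShapes <- function(g, inputShape) {
    shapes <- list()
    for (nd in g$nodes) {
        s <- switch(nd$op,
            input = inputShape,
            conv = {
                si <- shapes[[nd$inputs]]
                c(convOutDim(si[1], nd$params$k, nd$params$s, nd$params$p),
                  convOutDim(si[2], nd$params$k, nd$params$s, nd$params$p),
                  nd$params$out)
            },
            maxpool = ,
            avgpool = {
                si <- shapes[[nd$inputs]]
                c(convOutDim(si[1], nd$params$k, nd$params$s, nd$params$p),
                  convOutDim(si[2], nd$params$k, nd$params$s, nd$params$p),
                  si[3])
            },
            affine = ,
            relu = shapes[[nd$inputs]],
            add = {
                sa <- shapes[[nd$inputs[1]]]
                sb <- shapes[[nd$inputs[2]]]
                if (!identical(sa, sb))
                    stop(sprintf("shape mismatch at add node '%s'", nd$id))
                sa
            },
            concat = {
                ss <- lapply(nd$inputs, function(i) shapes[[i]])
                base <- ss[[1]][1:2]
                c(base, sum(vapply(ss, function(x) x[3], numeric(1))))
            },
            gap = {
                si <- shapes[[nd$inputs]]
                c(1L, 1L, si[3])
            },
            stop(sprintf("unknown op '%s'", nd$op))
        )
        if (any(s[1:2] < 1))
            stop(sprintf("node '%s' collapses the spatial extent", nd$id))
        shapes[[nd$id]] <- as.integer(s)
    }
    shapes
}

## ---- weight instantiation -------------------------------------------------

## Seeded He-normal weights for conv nodes; near-identity channelwise
## affines standing in for inference-time batch normalization.
graphWeights <- function(g, inputShape, seed) {
    shapes <- graphShapes(g, inputShape)
    withSeed(seed, {
        w <- list()
        for (nd in g$nodes) {
            if (nd$op == "conv") {
                cin <- shapes[[nd$inputs]][3]
                K <- nd$params$k^2 * cin
                w[[nd$id]] <- list(
                    W = matrix(stats::rnorm(nd$params$out * K,
                        sd = sqrt(2 / K)), nd$params$out, K),
                    b = numeric(nd$params$out))
            } else if (nd$op == "affine") {
                ch <- shapes[[nd$inputs]][3]
                w[[nd$id]] <- list(
                    scale = 1 + 0.05 * stats::rnorm(ch),
                    shift = 0.02 * stats::rnorm(ch))
            }
        }
        w
    })
}

## ---- forward operations ---------------------------------------------------

padSpatial <- function(A, p) {
    if (p == 0L) return(A)
    d <- dim(A)
    out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
    out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- A
    out
}

## Gather k x k patches of a padded [Hp, Wp, C] array into a (k*k*C) x P
## matrix, columns ordered with the output-row index fastest so that the
## GEMM result reshapes straight back into column-major [H', W', C'].
im2col <- function(Apad, k, s, Hout, Wout, C) {
    Hp <- dim(Apad)[1]; Wp <- dim(Apad)[2]
    offs <- as.vector(outer(0:(k - 1L),
        (0:(k - 1L)) * Hp, "+"))                 # dy fastest, then dx
    offs <- as.vector(outer(offs, (0:(C - 1L)) * Hp * Wp, "+"))
    ys <- (seq_len(Hout) - 1L) * s
    xs <- (seq_len(Wout) - 1L) * s
    base <- as.vector(outer(ys, xs * Hp, "+"))
    idx <- outer(offs, base, "+") + 1L
    matrix(Apad[idx], nrow = k * k * C)
}

convForward <- function(A, wt, k, s, p) {
    d <- dim(A)
    Hout <- convOutDim(d[1], k, s, p)
    Wout <- convOutDim(d[2], k, s, p)
    patches <- im2col(padSpatial(A, p), k, s, Hout, Wout, d[3])
    out <- wt$W %*% patches + wt$b
    array(t(out), c(Hout, Wout, nrow(wt$W)))
}

poolForward <- function(A, k, s, p, reduce) {
    d <- dim(A)
    Hout <- convOutDim(d[1], k, s, p)
    Wout <- convOutDim(d[2], k, s, p)
    Apad <- padSpatial(A, p)
    Hp <- dim(Apad)[1]; Wp <- dim(Apad)[2]
    offs <- as.vector(outer(0:(k - 1L), (0:(k - 1L)) * Hp, "+"))
    ys <- (seq_len(Hout) - 1L) * s
    xs <- (seq_len(Wout) - 1L) * s
    base <- as.vector(outer(ys, xs * Hp, "+"))
    idx <- outer(offs, base, "+") + 1L
    out <- array(0, c(Hout, Wout, d[3]))
    plane <- Hp * Wp
    for (ch in seq_len(d[3])) {
        m <- matrix(Apad[idx + (ch - 1L) * plane], nrow = k * k)
        r <- m[1L, ]
        if (reduce == "max") {
            for (j in 2:(k * k)) r <- pmax(r, m[j, ])
        } else {
            r <- colSums(m) / (k * k)
        }
        out[, , ch] <- r
    }
    out
}

affineForward <- function(A, wt) {
    d <- dim(A)
    plane <- d[1] * d[2]
    A * rep(wt$scale, each = plane) + rep(wt$shift, each = plane)
}

forwardGraph <- function(g, weights, x) {
    ## index of the last node consuming each activation, so spent
    ## activations can be dropped as the pass proceeds
    lastUse <- integer(0)
    for (i in seq_along(g$nodes))
        for (inp in g$nodes[[i]]$inputs) lastUse[inp] <- i
    acts <- list()
    out <- NULL
    step <- 0L
    for (nd in g$nodes) {
        step <- step + 1L
        out <- switch(nd$op,
            input = x,
            conv = convForward(acts[[nd$inputs]], weights[[nd$id]],
                nd$params$k, nd$params$s, nd$params$p),
            affine = affineForward(acts[[nd$inputs]], weights[[nd$id]]),
            relu = pmax(acts[[nd$inputs]], 0),
            maxpool = poolForward(acts[[nd$inputs]], nd$params$k,
                nd$params$s, nd$params$p, "max"),
            avgpool = poolForward(acts[[nd$inputs]], nd$params$k,
                nd$params$s, nd$params$p, "mean"),
            add = acts[[nd$inputs[1]]] + acts[[nd$inputs[2]]],
            concat = {
                parts <- acts[nd$inputs]
                d1 <- dim(parts[[1]])
                array(unlist(parts, use.names = FALSE),
                    c(d1[1], d1[2],
                      sum(vapply(parts, function(a) dim(a)[3], numeric(1)))))
            },
            gap = {
                A <- acts[[nd$inputs]]
                d <- dim(A)
                array(colMeans(matrix(A, d[1] * d[2], d[3])), c(1L, 1L, d[3]))
            }
        )
        acts[[nd$id]] <- out
        spent <- nd$inputs[!is.na(lastUse[nd$inputs]) &
            lastUse[nd$inputs] <= step]
        for (sp in spent) acts[[sp]] <- NULL
    }
    out
}

## ---- architecture builders ------------------------------------------------

## ResNet-101: 7x7/64 stem, 3-4-23-3 bottleneck stages with expansion 4,
## global average pooling -> 2048 channels.
buildResNet101 <- function() {
    g <- newGraph()
    addNode(g, "input", "input")
    addNode(g, "conv1", "conv", "input", k = 7L, s = 2L, p = 3L, out = 64L)
    addNode(g, "bn1", "affine", "conv1")
    addNode(g, "relu1", "relu", "bn1")
    prev <- addNode(g, "pool1", "maxpool", "relu1", k = 3L, s = 2L, p = 1L)
    inCh <- 64L
    stages <- list(c(64L, 3L, 1L), c(128L, 4L, 2L), c(256L, 23L, 2L),
        c(512L, 3L, 2L))
    for (si in seq_along(stages)) {
        f <- stages[[si]][1]; nb <- stages[[si]][2]; st <- stages[[si]][3]
        for (bi in seq_len(nb)) {
            s1 <- if (bi == 1L) st else 1L
            tag <- sprintf("s%db%d", si, bi)
            a <- addNode(g, paste0(tag, "_c1"), "conv", prev, k = 1L,
                s = 1L, p = 0L, out = f)
            a <- addNode(g, paste0(tag, "_n1"), "affine", a)
            a <- addNode(g, paste0(tag, "_r1"), "relu", a)
            a <- addNode(g, paste0(tag, "_c2"), "conv", a, k = 3L,
                s = s1, p = 1L, out = f)
            a <- addNode(g, paste0(tag, "_n2"), "affine", a)
            a <- addNode(g, paste0(tag, "_r2"), "relu", a)
            a <- addNode(g, paste0(tag, "_c3"), "conv", a, k = 1L,
                s = 1L, p = 0L, out = 4L * f)
            a <- addNode(g, paste0(tag, "_n3"), "affine", a)
            if (bi == 1L && (inCh != 4L * f || s1 != 1L)) {
                sc <- addNode(g, paste0(tag, "_sc"), "conv", prev, k = 1L,
                    s = s1, p = 0L, out = 4L * f)
                sc <- addNode(g, paste0(tag, "_scn"), "affine", sc)
            } else sc <- prev
            a <- addNode(g, paste0(tag, "_add"), "add", c(a, sc))
            prev <- addNode(g, paste0(tag, "_out"), "relu", a)
            inCh <- 4L * f
        }
    }
    addNode(g, "pool5", "gap", prev)
    g
}

## DenseNet-201: 7x7/64 stem, dense blocks of 6-12-48-32 layers with
## growth rate 32 and 1x1 bottlenecks (4x growth), halving transitions,
## global average pooling -> 1920 channels.
buildDenseNet201 <- function() {
    growth <- 32L
    g <- newGraph()
    addNode(g, "input", "input")
    addNode(g, "conv0", "conv", "input", k = 7L, s = 2L, p = 3L, out = 64L)
    addNode(g, "bn0", "affine", "conv0")
    addNode(g, "relu0", "relu", "bn0")
    prev <- addNode(g, "pool0", "maxpool", "relu0", k = 3L, s = 2L, p = 1L)
    ch <- 64L
    blocks <- c(6L, 12L, 48L, 32L)
    for (bi in seq_along(blocks)) {
        for (li in seq_len(blocks[bi])) {
            tag <- sprintf("d%dl%d", bi, li)
            a <- addNode(g, paste0(tag, "_n1"), "affine", prev)
            a <- addNode(g, paste0(tag, "_r1"), "relu", a)
            a <- addNode(g, paste0(tag, "_c1"), "conv", a, k = 1L, s = 1L,
                p = 0L, out = 4L * growth)
            a <- addNode(g, paste0(tag, "_n2"), "affine", a)
            a <- addNode(g, paste0(tag, "_r2"), "relu", a)
            a <- addNode(g, paste0(tag, "_c2"), "conv", a, k = 3L, s = 1L,
                p = 1L, out = growth)
            prev <- addNode(g, paste0(tag, "_cat"), "concat", c(prev, a))
            ch <- ch + growth
        }
        if (bi < length(blocks)) {
            tag <- sprintf("t%d", bi)
            a <- addNode(g, paste0(tag, "_n"), "affine", prev)
            a <- addNode(g, paste0(tag, "_r"), "relu", a)
            ch <- ch %/% 2L
            a <- addNode(g, paste0(tag, "_c"), "conv", a, k = 1L, s = 1L,
                p = 0L, out = ch)
            prev <- addNode(g, paste0(tag, "_p"), "avgpool", a, k = 2L,
                s = 2L, p = 0L)
        }
    }
    a <- addNode(g, "bn_final", "affine", prev)
    a <- addNode(g, "relu_final", "relu", a)
    addNode(g, "avg_pool", "gap", a)
    g
}

## NASNet-Large (6 normal cells per stack at base filter count 168, two
## reduction stages doubling the filters, cell output concatenating 6
## branches): penultimate global-average-pooling width
## 6 * 168 * 2^2 = 4032. Only this shape rule is registered; the cell
## search graph is not executed numerically.
nasnetLargeFeatureLength <- function(filters = 168L, branches = 6L,
                                     reductions = 2L) {
    as.integer(branches * filters * 2^reductions)
}
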