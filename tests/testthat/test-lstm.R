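# LSTM reference cell, batched layer equivalence, backprop correctness,
# training behaviour, prediction contracts, and the SVM baseline.

zeroCellWeights <- function(D, H) {
    z <- function() matrix(0, H, D)
    r <- function() matrix(0, H, H)
    list(I = list(u = z(), f = z(), w = z(), e = z()),
        R = list(u = r(), f = r(), w = r(), e = r()),
        b = list(u = numeric(H), f = numeric(H), w = numeric(H),
            e = numeric(H)))
}

test_that("a zero-weight cell has half-open gates and zero states", {
    st <- lstmCellStep(zeroCellWeights(3, 2), z = rnorm(3),
        prev = list(h = numeric(2), c = numeric(2)))
    expect_equal(st$u, rep(0.5, 2))
    expect_equal(st$f, rep(0.5, 2))
    expect_equal(st$e, rep(0.5, 2))
    expect_equal(st$w, rep(0, 2))
    expect_equal(st$c, rep(0, 2))
    expect_equal(st$h, rep(0, 2))
})

test_that("the scalar hand-evaluated step reproduces c = 0.5, h = 0.5 tanh(0.5)", {
    w <- list(I = list(u = matrix(1), f = matrix(1), w = matrix(1),
            e = matrix(1)),
        R = list(u = matrix(0), f = matrix(0), w = matrix(0),
            e = matrix(0)),
        b = list(u = 0, f = 0, w = 0, e = 0))
    st <- lstmCellStep(w, z = 0, prev = list(h = 0, c = 1))
    expect_equal(st$u, 0.5)
    expect_equal(st$f, 0.5)
    expect_equal(st$w, 0)
    expect_equal(st$e, 0.5)
    expect_equal(st$c, 0.5)
    expect_equal(st$h, 0.5 * tanh(0.5), tolerance = 1e-7)
    expect_equal(st$h, 0.23106, tolerance = 1e-4)
})

test_that("gate outputs stay in their ranges and |h| <= 1 on random instances", {
    set.seed(7)
    for (rep in 1:10) {
        H <- sample(1:4, 1); D <- sample(1:4, 1)
        w <- lapply(zeroCellWeights(D, H), function(part)
            lapply(part, function(p) p + rnorm(length(p), sd = 2)))
        st <- lstmCellStep(w, rnorm(D),
            list(h = rnorm(H), c = rnorm(H)))
        expect_true(all(st$u > 0 & st$u < 1))
        expect_true(all(st$f > 0 & st$f < 1))
        expect_true(all(st$e > 0 & st$e < 1))
        expect_true(all(st$w > -1 & st$w < 1))
        expect_true(all(abs(st$h) <= 1))
    }
})

test_that("the batched training layer agrees with the reference cell step", {
    # two independent code paths: per-gate reference recursion vs the
    # stacked-matrix layer used for training
    set.seed(11)
    H <- 5L; D <- 4L; Tn <- 6L; B <- 3L
    wts <- FRPSurv:::lstmInitWeights(D, H, 2L, seed = 99)
    X <- array(rnorm(B * Tn * D), c(B, Tn, D))
    fwd <- FRPSurv:::lstmDirectionForward(wts$fwd, X, H)
    cellW <- FRPSurv:::cellWeightsFromLayer(wts$fwd, H)
    for (bi in seq_len(B)) {
        st <- list(h = numeric(H), c = numeric(H))
        for (t in seq_len(Tn))
            st <- lstmCellStep(cellW, X[bi, t, ], st)
        expect_equal(unname(fwd$h[bi, ]), st$h, tolerance = 1e-5)
    }
    # and against the fully independent scalar oracle
    st2 <- list(h = numeric(H), c = numeric(H))
    for (t in seq_len(Tn))
        st2 <- oracleLSTMStep(wts$fwd$Wi, wts$fwd$Wr, wts$fwd$b,
            X[1, t, ], st2$h, st2$c, H)
    expect_equal(unname(fwd$h[1, ]), st2$h, tolerance = 1e-10)
})

test_that("analytic gradients match numerical differentiation", {
    set.seed(21)
    H <- 3L; D <- 4L; Tn <- 4L; B <- 3L
    cfg <- trainConfig(hiddenSize = H, seed = 1)
    wts <- FRPSurv:::lstmInitWeights(D, H, 2L, seed = 5,
        bidirectional = TRUE)
    X <- array(rnorm(B * Tn * D), c(B, Tn, D))
    Y <- matrix(0, B, 2); Y[cbind(1:B, c(1, 2, 1))] <- 1
    lossAt <- function(w) {
        P <- FRPSurv:::classifierForward(w, X, cfg)$scores
        -sum(log(P[Y == 1])) / B
    }
    fw <- FRPSurv:::classifierForward(wts, X, cfg, keep = TRUE)
    gr <- FRPSurv:::classifierBackward(wts, fw, X, Y, fw$scores, cfg)
    eps <- 1e-6
    for (nm in names(gr)) for (pn in names(gr[[nm]])) {
        param <- wts[[nm]][[pn]]
        probe <- sample(length(param), min(4, length(param)))
        for (ix in probe) {
            wp <- wts; wp[[nm]][[pn]][ix] <- param[ix] + eps
            wm <- wts; wm[[nm]][[pn]][ix] <- param[ix] - eps
            num <- (lossAt(wp) - lossAt(wm)) / (2 * eps)
            expect_equal(gr[[nm]][[pn]][ix], num, tolerance = 1e-4,
                info = paste(nm, pn, ix))
        }
    }
})

separableFRPs <- function(nPer = 8, M = 9, seed = 3) {
    # two texture families of valid FRP matrices (block structure vs
    # diffuse), built from memberships so all FRP constraints hold
    set.seed(seed)
    mk <- function(conc) {
        U <- matrix(rexp(M * 3)^conc, M, 3)
        U <- U / rowSums(U)
        maxMinCompose(U)
    }
    frps <- c(replicate(nPer, mk(3), simplify = FALSE),
        replicate(nPer, mk(0.2), simplify = FALSE))
    list(frps = frps, labels = rep(c("lt5", "gt5"), each = nPer))
}

test_that("training separates strongly structured FRP classes and the loss decreases", {
    d <- separableFRPs()
    mdl <- trainLSTM(d$frps, d$labels,
        trainConfig(hiddenSize = 20, seed = 2))
    log <- mdl@trainLog
    expect_gte(utils::tail(log$accuracy, 1), 0.95)
    # loss decreases over the first epochs
    expect_lt(mean(log$loss[seq(2, min(10, nrow(log)))]), log$loss[1])
    pr <- predictLSTM(mdl, d$frps)
    expect_gte(mean(pr$labels == d$labels), 0.95)
})

test_that("training with flipped labels flips the fitted decision", {
    d <- separableFRPs(nPer = 6, seed = 9)
    flipped <- ifelse(d$labels == "lt5", "gt5", "lt5")
    a <- trainLSTM(d$frps, d$labels, trainConfig(hiddenSize = 16, seed = 4))
    b <- trainLSTM(d$frps, flipped, trainConfig(hiddenSize = 16, seed = 4))
    pa <- predictLSTM(a, d$frps)$labels
    pb <- predictLSTM(b, d$frps)$labels
    expect_gte(mean(pa == d$labels), 0.95)
    expect_gte(mean(pb == flipped), 0.95)
})

test_that("softmax scores sum to one, ties go to the positive class, and batching does not matter", {
    d <- separableFRPs(nPer = 4, M = 7, seed = 13)
    mdl <- trainLSTM(d$frps, d$labels,
        trainConfig(hiddenSize = 8, maxEpochs = 30, seed = 6))
    pr <- predictLSTM(mdl, d$frps)
    expect_true(all(abs(rowSums(pr$scores) - 1) < 1e-6))
    # per-example inference equals whole-batch inference
    single <- vapply(seq_along(d$frps), function(i)
        predictLSTM(mdl, d$frps[i])$labels, character(1))
    expect_identical(unname(single), unname(pr$labels))
    # zero head weights force exact 0.5/0.5 scores: positive class wins
    tied <- mdl
    tied@weights$head$W[] <- 0
    tied@weights$head$b[] <- 0
    pt <- predictLSTM(tied, d$frps)
    expect_true(all(pt$scores == 0.5))
    expect_true(all(pt$labels == "gt5"))
})

test_that("batch sizes larger than the training set clamp to full batch", {
    d <- separableFRPs(nPer = 4, M = 7, seed = 17)
    expect_no_error(mdl <- trainLSTM(d$frps, d$labels,
        trainConfig(hiddenSize = 6, maxEpochs = 5, batchSize = 150,
            seed = 2)))
    expect_equal(mdl@M, 7L)
})

test_that("degenerate classifier inputs error cleanly", {
    d <- separableFRPs(nPer = 3, M = 6, seed = 19)
    expect_error(trainLSTM(d$frps, rep("gt5", 6)), "both classes")
    expect_error(trainLSTM(d$frps, d$labels[-1]), "one label per FRP")
    mixed <- c(d$frps[1:3], list(matrix(0.5, 4, 4)))
    expect_error(trainLSTM(mixed, c("a", "a", "b", "b")), "same size")
    mdl <- trainLSTM(d$frps, d$labels,
        trainConfig(hiddenSize = 4, maxEpochs = 3, seed = 1))
    expect_error(predictLSTM(mdl, list(matrix(1, 4, 4))),
        "does not match")
})

test_that("training is reproducible for a fixed seed", {
    d <- separableFRPs(nPer = 4, M = 7, seed = 23)
    a <- trainLSTM(d$frps, d$labels,
        trainConfig(hiddenSize = 6, maxEpochs = 20, seed = 8))
    b <- trainLSTM(d$frps, d$labels,
        trainConfig(hiddenSize = 6, maxEpochs = 20, seed = 8))
    expect_identical(predictLSTM(a, d$frps)$scores,
        predictLSTM(b, d$frps)$scores)
})

test_that("the linear SVM baseline separates separable toys and fails inseparable ones", {
    X <- rbind(matrix(rnorm(40, -3), 20, 2), matrix(rnorm(40, 3), 20, 2))
    y <- rep(c("lt5", "gt5"), each = 20)
    fit <- trainSVM(X, y)
    expect_equal(mean(predictSVM(fit, X) == y), 1.0)
    # identical features, opposite labels: nothing to learn
    X2 <- rbind(diag(2), diag(2))
    y2 <- c("lt5", "lt5", "gt5", "gt5")
    fit2 <- trainSVM(X2, y2)
    expect_equal(mean(predictSVM(fit2, X2) == y2), 0.5)
    expect_error(trainSVM(X, rep("gt5", 40)), "both classes")
})
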