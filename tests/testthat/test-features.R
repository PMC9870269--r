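# Backbone registry, preprocessing, deep-feature extraction, and the
# GLCM texture baseline.

test_that("backbone registry exposes the canonical contracts", {
    expect_setequal(listBackbones(),
        c("resnet101", "densenet201", "nasnetlarge"))
    rn <- backboneSpec("resnet101")
    dn <- backboneSpec("densenet201")
    nn <- backboneSpec("nasnetlarge")
    expect_identical(rn@inputSize, c(224L, 224L))
    expect_identical(dn@inputSize, c(224L, 224L))
    expect_identical(nn@inputSize, c(331L, 331L))
    expect_identical(featureLength(rn), 2048L)
    expect_identical(featureLength(dn), 1920L)
    expect_identical(featureLength(nn), 4032L)
    expect_identical(rn@extractionLayer, "pool5")
    expect_identical(dn@extractionLayer, "avg_pool")
    expect_identical(nn@extractionLayer, "global_average_pooling2d_2")
})

test_that("preprocessing resizes, replicates grayscale and normalizes deterministically", {
    img <- array(runif(100 * 80 * 3), c(100, 80, 3))
    A <- preprocessImage(img, "resnet101")
    expect_equal(dim(A), c(224L, 224L, 3L))
    # already at target size: only normalization applied, shape kept
    img224 <- array(runif(224 * 224 * 3), c(224, 224, 3))
    expect_equal(dim(preprocessImage(img224, "densenet201")),
        c(224L, 224L, 3L))
    # grayscale replicated to three identical channels pre-normalization
    gray <- matrix(runif(50 * 50), 50)
    A3 <- FRPSurv:::readImageArray(gray)
    expect_equal(A3[, , 1], A3[, , 2])
    expect_equal(A3[, , 2], A3[, , 3])
    # deterministic: no augmentation anywhere
    expect_identical(preprocessImage(img, "resnet101"),
        preprocessImage(img, "resnet101"))
})

test_that("extraction yields the architecture's feature length regardless of content", {
    img1 <- array(runif(64 * 64 * 3), c(64, 64, 3))
    img2 <- array(runif(96 * 48 * 3), c(96, 48, 3))
    model <- instantiateBackbone("resnet101", seed = 1)
    g1 <- extractCNNFeatures(img1, "resnet101", model = model)
    g2 <- extractCNNFeatures(img2, "resnet101", model = model)
    expect_length(g1, 2048)
    expect_length(g2, 2048)
    expect_true(all(is.finite(g1)))
    expect_identical(attr(g1, "backbone"), "resnet101")
    # same image, same model: identical features
    expect_identical(g1, extractCNNFeatures(img1, "resnet101",
        model = model))
})

test_that("external weights can be layered onto a backbone graph with shape checks", {
    m <- instantiateBackbone("resnet101", seed = 1)
    w <- m$weights$conv1$W
    m2 <- instantiateBackbone("resnet101", seed = 1,
        weights = list(conv1 = list(W = 2 * w)))
    expect_equal(m2$weights$conv1$W, 2 * w)
    expect_identical(m2$weights$bn1, m$weights$bn1)
    expect_error(instantiateBackbone("resnet101", seed = 1,
        weights = list(conv1 = list(W = matrix(0, 2, 2)))),
        "shape mismatch")
    expect_error(instantiateBackbone("resnet101", seed = 1,
        weights = list(nosuch = list(W = w))), "not a parameterized")
})

test_that("unknown extraction layers error listing the candidates", {
    img <- array(runif(32 * 32 * 3), c(32, 32, 3))
    expect_error(
        extractCNNFeatures(img, "resnet101", layer = "fc1000"),
        "candidates.*pool5")
    expect_error(instantiateBackbone("nasnetlarge"), "shape inference")
})

test_that("feature caches round-trip through CSV", {
    X <- matrix(rnorm(12), 3, 4)
    dir <- withr::local_tempdir()
    path <- file.path(dir, "cache.csv")
    writeFeatureCache(X, c("a", "b", "c"), "resnet101", path)
    back <- readFeatureCache(path)
    expect_equal(back$features, X, tolerance = 1e-12)
    expect_identical(back$imageIds, c("a", "b", "c"))
    expect_identical(back$backbone, "resnet101")
})

test_that("GLCM counts match brute-force pair enumeration", {
    # 4x4 checkerboard at 2 gray levels, distance 1, angle 0
    cb <- outer(1:4, 1:4, function(r, c) ((r + c) %% 2) * 0.99)
    G <- glcmMatrix(cb, nLevels = 2, distance = 1, angle = 0,
        symmetric = TRUE)
    expect_equal(G, oracleGLCMCounts(cb, 2, dr = 0, dc = 1))
    # every valid pair flips level along rows: zero diagonal, contrast 1
    expect_equal(sum(diag(G)), 0)
    h <- haralickFeatures(G)
    expect_equal(unname(h["contrast"]), 1)
    # random image, all four angles
    set.seed(3)
    img <- matrix(runif(100), 10)
    for (ang in c(0, 45, 90, 135)) {
        off <- switch(as.character(ang), "0" = c(0, 1), "45" = c(-1, 1),
            "90" = c(-1, 0), "135" = c(-1, -1))
        expect_equal(
            glcmMatrix(img, nLevels = 8, angle = ang),
            oracleGLCMCounts(img, 8, off[1], off[2]),
            info = paste("angle", ang))
    }
})

test_that("raw GLCMs are non-negative integer counts summing to the pair count, symmetric in symmetric mode", {
    set.seed(5)
    img <- matrix(runif(15 * 12), 15, 12)
    G <- glcmMatrix(img, nLevels = 8, angle = 0, symmetric = TRUE)
    expect_true(all(G >= 0))
    expect_true(all(G == round(G)))
    expect_equal(sum(G), 2 * 15 * 11)   # both orders of each valid pair
    expect_equal(G, t(G))
    Ga <- glcmMatrix(img, nLevels = 8, angle = 0, symmetric = FALSE)
    expect_equal(sum(Ga), 15 * 11)
})

test_that("the texture extractor returns exactly 14 finite features", {
    set.seed(6)
    f <- extractGLCMFeatures(matrix(runif(400), 20))
    expect_length(f, 14)
    expect_true(all(is.finite(f)))
    # RGB input goes through the luminance conversion
    rgb <- array(runif(20 * 20 * 3), c(20, 20, 3))
    expect_length(extractGLCMFeatures(rgb), 14)
})

test_that("a constant image gives the degenerate single-entry GLCM features", {
    f <- extractGLCMFeatures(matrix(0.4, 16, 16))
    expect_equal(unname(f["asm"]), 1)
    expect_equal(unname(f["contrast"]), 0)
    expect_equal(unname(f["variance"]), 0)
    expect_equal(unname(f["sum_variance"]), 0)
    expect_equal(unname(f["entropy"]), 0)
})

test_that("images smaller than the offset distance are rejected", {
    expect_error(glcmMatrix(matrix(0.5, 1, 1), distance = 1), "smaller")
    expect_error(extractGLCMFeatures(matrix(0.5, 2, 2), distance = 5),
        "smaller")
})
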