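# Cross-validation folds, confusion counting, and the metric formulas.

cohortLabels <- rep(c("lt5", "gt5"), c(29, 51))

test_that("stratified 10-fold split of the 29/51 cohort is a disjoint cover with 8 per fold", {
    folds <- kfoldSplit(cohortLabels, k = 10, seed = 3)
    expect_length(folds, 10)
    expect_true(all(lengths(folds) == 8))
    expect_identical(sort(unlist(folds)), 1:80)
    for (f in folds) {
        minority <- sum(cohortLabels[f] == "lt5")
        expect_true(minority %in% c(2, 3))  # 29 dealt across 10 folds
    }
})

test_that("fold proportions stay within one sample of the class ratio across seeds", {
    for (seed in 1:5) {
        folds <- kfoldSplit(cohortLabels, k = 10, seed = seed)
        expect_identical(sort(unlist(folds)), 1:80)
        counts <- vapply(folds, function(f)
            sum(cohortLabels[f] == "gt5"), numeric(1))
        expect_true(max(counts) - min(counts) <= 1)
    }
})

test_that("leave-one-out is the k = n limit", {
    y <- rep(c("lt5", "gt5"), each = 4)
    folds <- kfoldSplit(y, k = 8, stratified = FALSE, seed = 1)
    expect_true(all(lengths(folds) == 1))
    expect_identical(sort(unlist(folds)), 1:8)
})

test_that("invalid fold requests error", {
    expect_error(kfoldSplit(cohortLabels, k = 81), "k must be")
    expect_error(kfoldSplit(cohortLabels, k = 30), "minority")
})

test_that("confusion counts follow the positive-condition definitions", {
    y <- c("gt5", "gt5", "gt5", "lt5", "lt5")
    p <- c("gt5", "lt5", "gt5", "lt5", "gt5")
    cc <- confusionCounts(y, p)
    expect_equal(cc[["TP"]], 2)
    expect_equal(cc[["FN"]], 1)
    expect_equal(cc[["TN"]], 1)
    expect_equal(cc[["FP"]], 1)
    expect_equal(cc[["P"]], 3)
    expect_equal(cc[["N"]], 2)
    # perfect and fully wrong predictions
    perfect <- confusionCounts(y, y)
    expect_equal(perfect[["FP"]] + perfect[["FN"]], 0)
    flip <- ifelse(y == "gt5", "lt5", "gt5")
    wrong <- confusionCounts(y, flip)
    expect_equal(wrong[["TP"]] + wrong[["TN"]], 0)
    expect_error(confusionCounts(y, p[-1]), "equal length")
    expect_error(confusionCounts(c(y, "mid"), c(p, "mid")), "two-class")
})

test_that("metric formulas reproduce hand-computed values", {
    m <- computeMetrics(c(TP = 45, TN = 25, FP = 4, FN = 6))
    expect_equal(m[["ACC"]], 0.875)
    expect_equal(m[["PRE"]], 45 / 49)
    expect_equal(m[["SEN"]], 45 / 51)
    expect_equal(m[["SPE"]], 25 / 29)
    expect_equal(m[["F1"]], 2 * (45 / 49) * (45 / 51) /
        (45 / 49 + 45 / 51))
    perfect <- computeMetrics(c(TP = 51, TN = 29, FP = 0, FN = 0))
    expect_true(all(perfect == 1))
})

test_that("zero denominators yield NaN with a warning, never silent zero", {
    w <- capture_warnings(
        m <- computeMetrics(c(TP = 0, TN = 3, FP = 0, FN = 2)))
    expect_true(any(grepl("PRE undefined", w)))
    expect_true(any(grepl("F1 undefined", w)))
    expect_true(is.nan(m[["PRE"]]))
    w2 <- capture_warnings(
        m2 <- computeMetrics(c(TP = 0, TN = 3, FP = 0, FN = 0)))
    expect_true(any(grepl("SEN undefined", w2)))
    expect_true(is.nan(m2[["SEN"]]))
})

test_that("accuracy interpolates sensitivity and specificity; F1 is their precision-recall harmonic mean", {
    set.seed(4)
    for (rep in 1:20) {
        cc <- c(TP = sample(1:30, 1), TN = sample(1:30, 1),
            FP = sample(1:10, 1), FN = sample(1:10, 1))
        m <- computeMetrics(cc)
        expect_gte(m[["ACC"]], min(m[["SEN"]], m[["SPE"]]) - 1e-12)
        expect_lte(m[["ACC"]], max(m[["SEN"]], m[["SPE"]]) + 1e-12)
        expect_equal(m[["F1"]],
            2 / (1 / m[["PRE"]] + 1 / m[["SEN"]]), tolerance = 1e-12)
    }
})

test_that("the majority-class model scores the base rate under cross-validation", {
    X <- matrix(rnorm(80 * 3), 80, 3)
    rep <- runCVExperiment(X, cohortLabels, majorityModelSpec(), k = 10,
        seed = 5)
    expect_equal(metrics(rep)[["ACC"]], 51 / 80)
    expect_equal(metrics(rep)[["SEN"]], 1)
    expect_equal(metrics(rep)[["SPE"]], 0)
})

test_that("a perfect oracle model scores 1 and reports are seed-stable", {
    oracleSpec <- list(
        fit = function(x, labels, seed) NULL,
        predict = function(model, x) x)   # inputs are the labels
    rep1 <- runCVExperiment(cohortLabels, cohortLabels, oracleSpec,
        k = 10, seed = 2)
    expect_equal(metrics(rep1)[["ACC"]], 1)
    rep2 <- runCVExperiment(cohortLabels, cohortLabels, oracleSpec,
        k = 10, seed = 2)
    expect_identical(metrics(rep1), metrics(rep2))
    expect_identical(rep1@perFold, rep2@perFold)
})

test_that("pooled counts equal the sum of per-fold counts", {
    spec <- svmModelSpec()
    set.seed(6)
    X <- rbind(matrix(rnorm(29 * 4, 0), 29, 4),
        matrix(rnorm(51 * 4, 1.5), 51, 4))
    rep <- runCVExperiment(X, cohortLabels, spec, k = 10, seed = 7)
    pf <- rep@perFold
    for (nm in c("TP", "TN", "FP", "FN"))
        expect_equal(sum(pf[[nm]]), unname(confusion(rep)[[nm]]))
    # metrics recomputed from summed per-fold counts agree
    summed <- c(TP = sum(pf$TP), TN = sum(pf$TN), FP = sum(pf$FP),
        FN = sum(pf$FN))
    expect_equal(computeMetrics(summed), metrics(rep))
    # retained out-of-fold predictions reproduce the pooled counts
    preds <- rep@predictions
    expect_identical(nrow(preds), 80L)
    expect_equal(confusionCounts(preds$true, preds$predicted),
        confusion(rep))
})

test_that("metrics reports serialize to JSON", {
    rep <- runCVExperiment(cohortLabels, cohortLabels,
        list(fit = function(x, labels, seed) NULL,
            predict = function(model, x) x), k = 5, seed = 1)
    dir <- withr::local_tempdir()
    path <- file.path(dir, "report.json")
    writeMetricsReport(rep, path)
    back <- jsonlite::read_json(path, simplifyVector = TRUE)
    expect_equal(back$metrics$ACC, 1)
    expect_equal(back$counts$P, 51)
})
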