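#' Stratified k-fold split
#'
#' Partitions indices into k disjoint test folds covering every example
#' exactly once. With stratification (default) each class is shuffled
#' and dealt round-robin across folds, so per-fold class counts differ
#' by at most one from perfect proportionality.
#'
#' @param labels two-class label vector.
#' @param k number of folds.
#' @param stratified preserve the class ratio per fold.
#' @param seed shuffle seed.
#' @return list of k integer vectors (test indices per fold).
#' @examples
#' folds <- kfoldSplit(rep(c("lt5", "gt5"), c(29, 51)), k = 10, seed = 1)
#' lengths(folds)
#' @export
kfoldSplit <- function(labels, k = 10L, stratified = TRUE, seed = 1L) {
    n <- length(labels)
    k <- as.integer(k)
    if (k < 2L || k > n)
        stop(sprintf("k must be in [2, %d]", n), call. = FALSE)
    if (stratified && k > min(table(labels)))
        stop("stratified folds need k <= the minority class count",
            call. = FALSE)
    folds <- rep(list(integer(0)), k)
    if (stratified) {
        ## deal each class round-robin, continuing the fold counter
        ## across classes so fold totals also stay within one sample
        pos <- 0L
        cls <- 0L
        for (cl in unique(labels)) {
            ix <- which(labels == cl)
            ix <- withSeed(seed + cls, sample(ix))
            fo <- ((pos + seq_along(ix) - 1L) %% k) + 1L
            for (f in seq_len(k))
                folds[[f]] <- c(folds[[f]], ix[fo == f])
            pos <- pos + length(ix)
            cls <- cls + 1L
        }
    } else {
        ix <- withSeed(seed, sample.int(n))
        fo <- rep_len(seq_len(k), n)
        for (f in seq_len(k)) folds[[f]] <- ix[fo == f]
    }
    lapply(folds, sort)
}

#' Confusion counts for two-class survival prediction
#'
#' Counts with the longer-survival class as the positive condition:
#' TP and TN are correctly predicted positive and negative examples,
#' FP is a negative predicted positive, FN a positive predicted
#' negative; P = TP + FN and N = TN + FP.
#'
#' @param truth,predicted equal-length two-class label vectors.
#' @param positive positive-class label (default \code{"gt5"} when
#'   present).
#' @return named numeric with TP, TN, FP, FN, P, N.
#' @examples
#' confusionCounts(c("gt5", "gt5", "lt5"), c("gt5", "lt5", "lt5"))
#' @export
confusionCounts <- function(truth, predicted, positive = NULL) {
    truth <- as.character(truth); predicted <- as.character(predicted)
    if (length(truth) != length(predicted))
        stop("truth and predicted must have equal length", call. = FALSE)
    lev <- unique(c(truth, predicted))
    if (length(lev) > 2L)
        stop("labels must be two-class", call. = FALSE)
    if (is.null(positive)) positive <- if ("gt5" %in% lev) "gt5"
        else sort(lev)[length(lev)]
    tpos <- truth == positive
    ppos <- predicted == positive
    out <- c(TP = sum(tpos & ppos), TN = sum(!tpos & !ppos),
        FP = sum(!tpos & ppos), FN = sum(tpos & !ppos))
    c(out, P = unname(out["TP"] + out["FN"]),
        N = unname(out["TN"] + out["FP"]))
}

#' Performance metrics from confusion counts
#'
#' Accuracy (TP+TN)/(P+N), sensitivity TP/P, specificity TN/N, precision
#' TP/(TP+FP) and F1 = 2 PRE SEN / (PRE + SEN). A zero denominator makes
#' the affected metric NaN with a warning, never a silent 0.
#'
#' @param counts named vector from \code{\link{confusionCounts}} (TP,
#'   TN, FP, FN at minimum).
#' @return named numeric: ACC, SEN, SPE, PRE, F1.
#' @examples
#' computeMetrics(c(TP = 45, TN = 25, FP = 4, FN = 6))
#' @export
computeMetrics <- function(counts) {
    TP <- counts[["TP"]]; TN <- counts[["TN"]]
    FP <- counts[["FP"]]; FN <- counts[["FN"]]
    P <- TP + FN; N <- TN + FP
    safe <- function(num, den, what) {
        if (den == 0) {
            warning(sprintf("%s undefined: zero denominator", what),
                call. = FALSE)
            NaN
        } else num / den
    }
    ACC <- safe(TP + TN, P + N, "ACC")
    SEN <- safe(TP, P, "SEN")
    SPE <- safe(TN, N, "SPE")
    PRE <- safe(TP, TP + FP, "PRE")
    F1 <- if (!is.nan(PRE) && !is.nan(SEN) && (PRE + SEN) > 0)
        2 * PRE * SEN / (PRE + SEN)
    else {
        warning("F1 undefined: zero denominator", call. = FALSE)
        NaN
    }
    c(ACC = ACC, SEN = SEN, SPE = SPE, PRE = PRE, F1 = F1)
}

#' Cross-validated experiment
#'
#' Runs a stratified k-fold cross-validation of a model specification
#' over a dataset: for each fold, the model is trained on the remaining
#' folds and predicts the held-out fold; out-of-fold predictions are
#' pooled into a single confusion table for the headline metrics, and a
#' per-fold breakdown is retained. Fully seeded: fold assignment and
#' every per-fold training run derive from \code{seed}.
#'
#' @param x dataset: a list of per-example inputs (e.g. FRPs) or a
#'   numeric matrix with one row per example.
#' @param labels two-class labels, one per example.
#' @param modelSpec list with functions \code{fit(x, labels, seed)} and
#'   \code{predict(model, x)} returning predicted labels; see
#'   \code{\link{lstmModelSpec}}, \code{\link{svmModelSpec}},
#'   \code{\link{majorityModelSpec}}.
#' @param k number of folds.
#' @param stratified stratify folds by class.
#' @param seed global seed for folds and per-fold training.
#' @param positive positive-class label (default \code{"gt5"} when
#'   present).
#' @return A \linkS4class{MetricsReport}.
#' @export
runCVExperiment <- function(x, labels, modelSpec, k = 10L,
                            stratified = TRUE, seed = 1L,
                            positive = NULL) {
    labels <- as.character(labels)
    n <- length(labels)
    takeRows <- function(obj, ix)
        if (is.matrix(obj)) obj[ix, , drop = FALSE] else obj[ix]
    if (if (is.matrix(x)) nrow(x) != n else length(x) != n)
        stop("x and labels must have matching sizes", call. = FALSE)
    seeds <- deriveSeeds(seed, k + 1L)
    folds <- kfoldSplit(labels, k = k, stratified = stratified,
        seed = seeds[k + 1L])
    predicted <- character(n)
    perFold <- vector("list", k)
    for (f in seq_len(k)) {
        test <- folds[[f]]
        train <- setdiff(seq_len(n), test)
        model <- tryCatch(
            modelSpec$fit(takeRows(x, train), labels[train], seeds[f]),
            error = function(e) stop(sprintf(
                "fold %d training failed: %s", f, conditionMessage(e)),
                call. = FALSE))
        pred <- modelSpec$predict(model, takeRows(x, test))
        predicted[test] <- pred
        cc <- confusionCounts(labels[test], pred, positive = positive)
        perFold[[f]] <- data.frame(fold = f, t(cc),
            ACC = (cc[["TP"]] + cc[["TN"]]) / length(test))
    }
    counts <- confusionCounts(labels, predicted, positive = positive)
    foldOf <- integer(n)
    for (f in seq_len(k)) foldOf[folds[[f]]] <- f
    new("MetricsReport", counts = counts,
        metrics = computeMetrics(counts),
        perFold = do.call(rbind, perFold),
        predictions = data.frame(index = seq_len(n), fold = foldOf,
            true = labels, predicted = predicted))
}

#' Model specifications for the cross-validation harness
#'
#' \code{lstmModelSpec} trains the FRP-sequence bidirectional LSTM,
#' \code{svmModelSpec} the linear SVM baseline on feature rows, and
#' \code{majorityModelSpec} the deterministic always-predict-majority
#' baseline. Each returns the \code{fit}/\code{predict} pair consumed by
#' \code{\link{runCVExperiment}}; the per-fold seed is passed into
#' \code{fit} so every fold's training is independently seeded.
#'
#' @param config a \code{\link{trainConfig}} for the LSTM.
#' @param positive positive-class label convention passed through.
#' @param cost SVM cost parameter.
#' @return list with \code{fit} and \code{predict} functions.
#' @export
lstmModelSpec <- function(config = trainConfig(), positive = NULL) {
    list(
        fit = function(x, labels, seed) {
            cfg <- config
            cfg$seed <- as.integer(seed %% 2147483647)
            trainLSTM(x, labels, cfg, positive = positive)
        },
        predict = function(model, x) predictLSTM(model, x)$labels)
}

#' @rdname lstmModelSpec
#' @export
svmModelSpec <- function(positive = NULL, cost = 1) {
    list(
        fit = function(x, labels, seed)
            trainSVM(x, labels, positive = positive, cost = cost),
        predict = function(model, x) predictSVM(model, x))
}

#' @rdname lstmModelSpec
#' @export
majorityModelSpec <- function() {
    list(
        fit = function(x, labels, seed) {
            tab <- table(labels)
            names(tab)[which.max(tab)]
        },
        predict = function(model, x) {
            n <- if (is.matrix(x)) nrow(x) else length(x)
            rep(model, n)
        })
}

#' Write a metrics report
#'
#' Exports a \linkS4class{MetricsReport} as JSON (counts, metrics and
#' the per-fold table).
#'
#' @param report a \linkS4class{MetricsReport}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
    stopifnot(is(report, "MetricsReport"))
    jsonlite::write_json(list(
        counts = as.list(report@counts),
        metrics = as.list(report@metrics),
        perFold = report@perFold,
        predictions = report@predictions
    ), path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}
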