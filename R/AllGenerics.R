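#' Accessors for FuzzyPartition and FRP objects
#'
#' \code{memberships}, \code{centers}, \code{converged} and
#' \code{objectiveTrace} extract the corresponding slots of a
#' \linkS4class{FuzzyPartition}; \code{frpMatrix} returns the plain
#' numeric matrix of an \linkS4class{FRP}; \code{metrics} and
#' \code{confusion} extract the metric vector and confusion counts of a
#' \linkS4class{MetricsReport}.
#'
#' @param object an object of the documented class.
#' @return The slot contents (matrix, numeric vector or logical).
#' @name accessors
#' @aliases memberships centers converged objectiveTrace frpMatrix
#'   metrics confusion
NULL

#' @rdname accessors
#' @export
setGeneric("memberships", function(object) standardGeneric("memberships"))

#' @rdname accessors
#' @export
setGeneric("centers", function(object) standardGeneric("centers"))

#' @rdname accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))

#' @rdname accessors
#' @export
setGeneric("objectiveTrace",
    function(object) standardGeneric("objectiveTrace"))

#' @rdname accessors
#' @export
setGeneric("frpMatrix", function(object) standardGeneric("frpMatrix"))

#' @rdname accessors
#' @export
setGeneric("metrics", function(object) standardGeneric("metrics"))

#' @rdname accessors
#' @export
setGeneric("confusion", function(object) standardGeneric("confusion"))

#' @rdname accessors
#' @export
setMethod("memberships", "FuzzyPartition", function(object)
    object@memberships)

#' @rdname accessors
#' @export
setMethod("centers", "FuzzyPartition", function(object) object@centers)

#' @rdname accessors
#' @export
setMethod("converged", "FuzzyPartition", function(object) object@converged)

#' @rdname accessors
#' @export
setMethod("objectiveTrace", "FuzzyPartition", function(object)
    object@objectiveTrace)

#' @rdname accessors
#' @export
setMethod("frpMatrix", "FRP", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("metrics", "MetricsReport", function(object) object@metrics)

#' @rdname accessors
#' @export
setMethod("confusion", "MetricsReport", function(object) object@counts)

#' @describeIn accessors dimensions of the FRP matrix.
#' @export
setMethod("dim", "FRP", function(x) dim(x@values))

setMethod("show", "FCMConfig", function(object) {
    cat(sprintf(
        "FCMConfig: c = %d, m = %g, delta = %g, maxIter = %d, seed = %d\n",
        object@c, object@m, object@delta, object@maxIter, object@seed))
})

setMethod("show", "FuzzyPartition", function(object) {
    cat(sprintf(
        "FuzzyPartition: %d points, %d clusters (dim %d)\n",
        nrow(object@memberships), ncol(object@memberships),
        ncol(object@centers)))
    cat(sprintf("  iterations: %d (%s)\n", object@nIterations,
        if (object@converged) "converged" else "iteration cap reached"))
    cat(sprintf("  final objective: %.6g\n",
        utils::tail(object@objectiveTrace, 1)))
})

setMethod("show", "FRP", function(object) {
    cat(sprintf("FRP: %d x %d fuzzy recurrence plot (c = %d, m = %g)\n",
        nrow(object@values), ncol(object@values), object@clusters,
        object@exponent))
    cat(sprintf("  off-diagonal range: [%.3f, %.3f]\n",
        min(object@values[row(object@values) != col(object@values)]),
        max(object@values[row(object@values) != col(object@values)])))
})

setMethod("show", "BackboneSpec", function(object) {
    cat(sprintf("BackboneSpec '%s'\n", object@name))
    cat(sprintf("  input size: %d x %d x 3\n", object@inputSize[1],
        object@inputSize[2]))
    cat(sprintf("  extraction layer: %s (global average pooling)\n",
        object@extractionLayer))
    cat(sprintf("  flattened feature length: %d\n", object@featureLength))
    cat(sprintf("  forward pass available: %s\n", object@forwardAvailable))
})

setMethod("show", "BiLSTMClassifier", function(object) {
    cat(sprintf(
        "BiLSTMClassifier: %d time steps x %d features, hidden size %d\n",
        object@M, object@M, object@config$hiddenSize))
    cat(sprintf("  classes: %s (positive: %s)\n",
        paste(object@classLevels, collapse = " / "),
        object@classLevels[2]))
    n <- nrow(object@trainLog)
    if (n > 0)
        cat(sprintf("  trained %d epochs, final loss %.4g, accuracy %.3f\n",
            n, object@trainLog$loss[n], object@trainLog$accuracy[n]))
})

setMethod("show", "MetricsReport", function(object) {
    cc <- object@counts
    mm <- object@metrics
    cat("MetricsReport (pooled out-of-fold confusion counts)\n")
    cat(sprintf("  TP = %d  FN = %d  (P = %d)\n", cc[["TP"]], cc[["FN"]],
        cc[["P"]]))
    cat(sprintf("  TN = %d  FP = %d  (N = %d)\n", cc[["TN"]], cc[["FP"]],
        cc[["N"]]))
    cat(sprintf(
        "  ACC = %.4f  SEN = %.4f  SPE = %.4f  PRE = %.4f  F1 = %.4f\n",
        mm[["ACC"]], mm[["SEN"]], mm[["SPE"]], mm[["PRE"]], mm[["F1"]]))
    if (nrow(object@perFold) > 0)
        cat(sprintf("  folds: %d (per-fold ACC %.3f +/- %.3f)\n",
            nrow(object@perFold), mean(object@perFold$ACC),
            stats::sd(object@perFold$ACC)))
})
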