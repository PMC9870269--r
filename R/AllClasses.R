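#' @import methods
NULL

#' Fuzzy c-means configuration
#'
#' Holds the parameters of a fuzzy c-means (FCM) run: the number of
#' clusters \code{c}, the fuzzy weighting exponent \code{m}, the
#' convergence threshold \code{delta} on the maximum absolute elementwise
#' change of the membership matrix, the iteration cap \code{maxIter}, and
#' the seed of the random (symmetric Dirichlet) membership initialization.
#'
#' @slot c integer(1), number of clusters (>= 1).
#' @slot m numeric(1), fuzzy weighting exponent (> 1).
#' @slot delta numeric(1), convergence threshold (> 0).
#' @slot maxIter integer(1), maximum number of iterations (>= 1).
#' @slot seed integer(1), RNG seed for the membership initialization.
#' @exportClass FCMConfig
setClass("FCMConfig",
    representation(
        c = "integer",
        m = "numeric",
        delta = "numeric",
        maxIter = "integer",
        seed = "integer"
    )
)

setValidity("FCMConfig", function(object) {
    msg <- character()
    if (length(object@c) != 1L || is.na(object@c) || object@c < 1L)
        msg <- c(msg, "'c' must be a single integer >= 1")
    if (length(object@m) != 1L || !is.finite(object@m) || object@m <= 1)
        msg <- c(msg, "'m' must be a single number > 1")
    if (length(object@delta) != 1L || !is.finite(object@delta) ||
        object@delta <= 0)
        msg <- c(msg, "'delta' must be a single number > 0")
    if (length(object@maxIter) != 1L || is.na(object@maxIter) ||
        object@maxIter < 1L)
        msg <- c(msg, "'maxIter' must be a single integer >= 1")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "'seed' must be a single integer")
    if (length(msg)) msg else TRUE
})

#' Fuzzy partition returned by fcmFit
#'
#' The result of a fuzzy c-means run: a membership matrix with one row per
#' data point and one column per cluster (rows sum to 1), the cluster
#' centers (one row per cluster), the number of iterations performed,
#' whether the membership change fell below the threshold, and the trace
#' of the weighted within-cluster objective across iterations.
#'
#' @slot memberships numeric matrix, points x clusters, rows sum to 1.
#' @slot centers numeric matrix, clusters x data dimension.
#' @slot nIterations integer(1), iterations performed.
#' @slot converged logical(1), TRUE if the membership change fell below
#'   \code{delta} before the iteration cap.
#' @slot objectiveTrace numeric, objective value after each update pair.
#' @exportClass FuzzyPartition
setClass("FuzzyPartition",
    representation(
        memberships = "matrix",
        centers = "matrix",
        nIterations = "integer",
        converged = "logical",
        objectiveTrace = "numeric"
    )
)

setValidity("FuzzyPartition", function(object) {
    U <- object@memberships
    msg <- character()
    if (!is.numeric(U) || any(!is.finite(U)))
        msg <- c(msg, "memberships must be finite numeric")
    else {
        if (any(U < -1e-12) || any(U > 1 + 1e-12))
            msg <- c(msg, "memberships must lie in [0, 1]")
        if (any(abs(rowSums(U) - 1) > 1e-9))
            msg <- c(msg, "membership rows must sum to 1 (tolerance 1e-9)")
    }
    if (nrow(object@centers) != ncol(U))
        msg <- c(msg, "one center per membership column required")
    if (length(msg)) msg else TRUE
})

#' Fuzzy recurrence plot
#'
#' A square matrix of fuzzy similarity grades between embedded phase-space
#' states, with unit diagonal (reflexivity), symmetry, and entries in
#' [0, 1] obtained by max-min composition of FCM memberships.
#'
#' @slot values numeric M x M matrix in [0, 1].
#' @slot clusters integer(1), number of FCM clusters used.
#' @slot exponent numeric(1), fuzzy exponent used.
#' @exportClass FRP
setClass("FRP",
    representation(
        values = "matrix",
        clusters = "integer",
        exponent = "numeric"
    )
)

setValidity("FRP", function(object) {
    Fm <- object@values
    msg <- character()
    if (nrow(Fm) != ncol(Fm))
        msg <- c(msg, "FRP must be square")
    if (any(!is.finite(Fm)) || any(Fm < -1e-12) || any(Fm > 1 + 1e-12))
        msg <- c(msg, "FRP entries must be finite and in [0, 1]")
    if (any(abs(diag(Fm) - 1) > 1e-12))
        msg <- c(msg, "FRP diagonal must equal 1")
    if (max(abs(Fm - t(Fm))) > 1e-12)
        msg <- c(msg, "FRP must be symmetric")
    if (length(msg)) msg else TRUE
})

#' Backbone architecture specification
#'
#' Registry entry for a pretrained-style convolutional backbone: its
#' canonical input size, the role of the extraction layer (the final
#' global-average-pooling layer before the fully-connected head), the
#' historical layer-name alias, the flattened feature length that layer
#' yields, and whether an in-package forward pass is available.
#'
#' @slot name character(1), backbone identifier.
#' @slot inputSize integer(2), height and width of the canonical RGB input.
#' @slot extractionLayer character(1), alias of the extraction layer.
#' @slot featureLength integer(1), flattened length at the extraction layer.
#' @slot forwardAvailable logical(1), TRUE if the in-package layer graph
#'   supports a numerical forward pass.
#' @exportClass BackboneSpec
setClass("BackboneSpec",
    representation(
        name = "character",
        inputSize = "integer",
        extractionLayer = "character",
        featureLength = "integer",
        forwardAvailable = "logical"
    )
)

#' Bidirectional LSTM classifier
#'
#' A trained bidirectional LSTM sequence classifier over fuzzy recurrence
#' plots: the gate weights of both directions, the softmax head, the
#' training configuration, the class levels (second level is the positive
#' class), and the per-epoch training log.
#'
#' @slot weights list of weight matrices for both directions and the head.
#' @slot config list, the training configuration used.
#' @slot classLevels character(2), class labels; the second is positive.
#' @slot M integer(1), sequence length / feature count of the input FRPs.
#' @slot trainLog data.frame with epoch, loss and training accuracy.
#' @exportClass BiLSTMClassifier
setClass("BiLSTMClassifier",
    representation(
        weights = "list",
        config = "list",
        classLevels = "character",
        M = "integer",
        trainLog = "data.frame"
    )
)

#' Cross-validated performance report
#'
#' Confusion counts pooled over out-of-fold predictions together with the
#' derived metrics (accuracy, sensitivity, specificity, precision, F1),
#' and a per-fold breakdown.
#'
#' @slot counts named numeric: TP, TN, FP, FN, P, N.
#' @slot metrics named numeric: ACC, SEN, SPE, PRE, F1.
#' @slot perFold data.frame of per-fold counts and metrics (may be empty).
#' @slot predictions data.frame of out-of-fold predictions (index, fold,
#'   true, predicted; may be empty).
#' @exportClass MetricsReport
setClass("MetricsReport",
    representation(
        counts = "numeric",
        metrics = "numeric",
        perFold = "data.frame",
        predictions = "data.frame"
    ),
    prototype(perFold = data.frame(), predictions = data.frame())
)

setValidity("MetricsReport", function(object) {
    need <- c("TP", "TN", "FP", "FN", "P", "N")
    if (!all(need %in% names(object@counts)))
        return("counts must contain TP, TN, FP, FN, P, N")
    cc <- object@counts
    if (cc[["P"]] != cc[["TP"]] + cc[["FN"]] ||
        cc[["N"]] != cc[["TN"]] + cc[["FP"]])
        return("P and N must be consistent with TP/FN and TN/FP")
    TRUE
})
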