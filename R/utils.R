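## Internal seeded-evaluation helpers. Every stochastic step in the package
## runs through withSeed() so that a single pipeline seed fans out
## deterministically without disturbing the caller's RNG stream.

withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Derive n child seeds from one parent seed (all < 2^31).
deriveSeeds <- function(seed, n) {
    withSeed(seed, sample.int(2147483646L, n))
}

stopIfNotFinite <- function(x, what) {
    if (!is.numeric(x) || any(!is.finite(x)))
        stop(sprintf("%s must be finite numeric, without NA/NaN/Inf", what),
            call. = FALSE)
    invisible(x)
}

asPointMatrix <- function(x) {
    if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
    if (!is.matrix(x)) x <- as.matrix(x)
    storage.mode(x) <- "double"
    if (nrow(x) == 0L) stop("no data points supplied", call. = FALSE)
    stopIfNotFinite(x, "data points")
    x
}
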