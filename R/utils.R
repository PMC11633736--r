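# Internal helpers.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv()))
                    rm(".Random.seed", envir = globalenv())
            } else assign(".Random.seed", old, envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

# Deterministic per-pixel seed derived from a global seed and pixel index.
# Integer mixing done in doubles (exact below 2^53), reduced below 2^31.
pixelSeed <- function(seed, y, x) {
    s <- (abs(as.numeric(seed)) %% 2147483647) + 1
    h <- (s * 48271 + y * 69621 + x * 16807) %% 2147483629
    as.integer(h)
}

assertScalar <- function(x, name, positive = TRUE, strict = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop(sprintf("'%s' must be a single finite number", name),
             call. = FALSE)
    if (positive && (if (strict) x <= 0 else x < 0))
        stop(sprintf("'%s' must be %s", name,
                     if (strict) "> 0" else ">= 0"), call. = FALSE)
    invisible(x)
}

# sigma of a Gaussian from its full width at half maximum
fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
sigmaToFwhm <- function(sigma) sigma * 2 * sqrt(2 * log(2))

# pixel-center coordinate axes (um) for an n-pixel dimension, origin at the
# field center
centeredAxis <- function(n, pixelSize) (seq_len(n) - (n + 1) / 2) * pixelSize
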