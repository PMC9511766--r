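# Internal helpers shared across modules.

## Evaluate `expr` under a fixed RNG state without disturbing the caller's
## stream. All stochastic entry points funnel through this, which is what
## makes every generator a pure function of (config, seed).
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    force(expr)
}

## Round half *up* to one decimal (percent reporting convention); base R's
## round() is half-to-even, which disagrees on values like 38.85.
roundHalfUp1 <- function(x) floor(x * 10 + 0.5) / 10

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
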