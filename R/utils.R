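## Internal helpers shared across modules.

## Tight bounding box of a logical mask in 0-based half-open (x0,y0,x1,y1)
## coordinates; x runs over columns, y over rows.
tightBBox <- function(mask) {
    w <- which(mask, arr.ind = TRUE)
    if (nrow(w) == 0L) return(c(0, 0, 0, 0))
    c(min(w[, 2]) - 1, min(w[, 1]) - 1, max(w[, 2]), max(w[, 1]))
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

## Evaluate expr under a temporary RNG seed, restoring the caller's RNG
## state afterwards so package randomness never leaks into user code.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Deterministic per-scene seed derived from a master seed; kept within
## 32-bit integer range.
deriveSeed <- function(masterSeed, i) {
    as.integer((as.numeric(masterSeed) * 48271 + i * 16807) %% 2147483647L)
}

## Population (not sample) standard deviation.
popSD <- function(x) sqrt(mean((x - mean(x))^2))
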