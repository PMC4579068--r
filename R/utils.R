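#' @keywords internal
"_PACKAGE"

#' @importFrom stats optim optimise pchisq rexp runif setNames
#' @importFrom utils head tail combn
NULL

## Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Deterministic per-replicate substream seed (kept below 2^31 - 1).
substream_seed <- function(seed, r) {
  s <- (as.numeric(seed) + 7919 * as.numeric(r)) %% 2147483587
  as.integer(s + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
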