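## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the current `.Random.seed`, seeds the generator, evaluates `expr`,
#' and restores the previous RNG state so callers' random streams are not
#' disturbed. Used wherever a reproducible sub-stream is required (fixed-seed
#' validation pair streams, per-spectrum Monte-Carlo-dropout draws).
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## Deterministic 32-bit-safe integer hash of a string; used to derive
## per-spectrum sub-seeds from a run seed.
hash_string <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

## Mixes a base seed with one or more integers into a seed < 2^31.
derive_seed <- function(seed, ...) {
  extra <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (e in extra) h <- (h * 48271 + as.numeric(e) + 1) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}
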