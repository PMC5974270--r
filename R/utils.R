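`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with one or more integer keys through a multiplicative
#' congruential step, yielding a stable seed below 2^31. Used so that every
#' trial, Monte-Carlo run and shuffle gets its own substream: extending the
#' number of runs never changes earlier draws.
#'
#' @param seed master integer seed
#' @param ... integer keys (e.g. trial index, run index)
#' @return a single integer seed
#' @export
derive_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483629
  for (k in c(...)) h <- (h * 48271 + as.double(k) + 1) %% 2147483629
  as.integer(h + 1)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}
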