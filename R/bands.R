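#' Canonical LFP frequency band definitions
#'
#' The five bands used throughout the pipeline: theta 4-8, alpha 8-15,
#' beta 15-30, low gamma 30-60 and high gamma 60-100 Hz. Edges are half-open
#' `[lo, hi)` so that shared edges (8, 15, 30, 60 Hz) are never counted twice
#' and the five bands tile `[4, 100)` exactly once.
#'
#' @param bands optional character vector selecting (and ordering) a subset of
#'   band names; `NULL` returns all five.
#' @return a data frame with columns `name`, `lo`, `hi` (Hz).
#' @examples
#' band_definitions()
#' band_definitions("theta")
#' @export
band_definitions <- function(bands = NULL) {
  defs <- data.frame(
    name = c("theta", "alpha", "beta", "low_gamma", "high_gamma"),
    lo   = c(4, 8, 15, 30, 60),
    hi   = c(8, 15, 30, 60, 100),
    stringsAsFactors = FALSE
  )
  if (is.null(bands)) return(defs)
  miss <- setdiff(bands, defs$name)
  if (length(miss)) {
    stop("unknown band(s): ", paste(miss, collapse = ", "))
  }
  defs[match(bands, defs$name), , drop = FALSE]
}
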