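#' Derive a stage-specific seed from a global seed
#'
#' A single pipeline seed fans out to per-stage seeds through a fixed,
#' documented arithmetic so any stage can be re-run in isolation and still
#' reproduce its in-pipeline result. The derivation is
#' `(seed * 7919 + 131 * sum(utf8(stage))) mod (2^31 - 1)`, kept strictly
#' below 2^31 so it is always a valid R integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage label, e.g. `"fit:positive"`.
#' @return an integer seed.
#' @export
#' @examples
#' derive_seed(1, "fit:positive")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- (as.double(seed) * 7919 + 131 * sum(utf8ToInt(stage))) %% 2147483647
  as.integer(h)
}

# Population-convention standard deviation (denominator n, not n-1).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Column-wise population SDs without an apply loop (hot path in resampling).
col_pop_sd <- function(m) sqrt(pmax(0, colMeans(m * m) - colMeans(m)^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stop with a formatted message, no call in the condition.
fail <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
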