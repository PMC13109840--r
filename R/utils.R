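#' Convert a Gaussian FWHM to its standard deviation
#'
#' @param fwhm Full width at half maximum (same units as the returned sigma).
#' @return `fwhm / (2 * sqrt(2 * log(2)))`, i.e. FWHM / 2.3548.
#' @export
fwhmToSigma <- function(fwhm) {
  stopifnot(is.numeric(fwhm), all(fwhm >= 0))
  fwhm / (2 * sqrt(2 * log(2)))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.  All generators in the package route
# their randomness through this so that a seed fully determines an output.
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Derive a stream-specific child seed from a base seed, staying inside the
# 32-bit integer range R requires.
childSeed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream * 1009) %% 2147483647
}
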