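#' Derive a reproducible sub-seed from a master seed and a component name
#'
#' One master seed drives named substreams (tree, traits, noise, ...) so a
#' single component can be re-randomised without disturbing the others. The
#' result always fits a 32-bit integer.
#'
#' @param seed Master integer seed.
#' @param name Component name.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# z-score standardisation that tolerates data.frame input
zscore <- function(x) (x - mean(x)) / stats::sd(x)

# Restore the caller's global RNG state when `envir`'s frame exits, so
# explicitly-seeded functions don't clobber an enclosing simulation stream.
local_rng <- function(envir = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  expr <- if (is.null(old)) {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible(old)
}
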