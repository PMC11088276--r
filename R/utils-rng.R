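# Deterministic seed substreams and a small string hash.
#
# Every generator draws from its own named substream derived from the single
# user-supplied seed, so adding or reordering generators never perturbs
# another generator's stream.

# Polynomial rolling hash of a string, modulo 2^31 - 1 (Mersenne prime).
# Arithmetic stays below 2^53 so results are exact in doubles.
.str_hash <- function(x) {
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% m
  h
}

#' Derive a deterministic integer seed for a named substream
#'
#' Combines a user-supplied integer seed with a stream name so that each
#' generator in the package owns an independent, reproducible RNG stream.
#' The result is always in `[0, 2^31 - 2]`.
#'
#' @param seed Integer master seed.
#' @param name Character stream name (e.g. `"screen"`, `"bends"`).
#' @return A single integer usable with [set.seed()].
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed),
            is.character(name), length(name) == 1)
  m <- 2147483647
  h <- .str_hash(name)
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

# Evaluate `expr` under the substream RNG, restoring the caller's RNG state.
with_substream <- function(seed, name, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(substream_seed(seed, name))
  }
  force(expr)
}

# FNV-1a-flavoured 31-bit hash of an arbitrary object's JSON rendering;
# used to stamp pipeline outputs with a config fingerprint.
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                     null = "null", force = TRUE))
  sprintf("%08x", .str_hash(s))
}
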