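#' Derive a reproducible sub-seed
#'
#' Deterministically mixes a base seed with an arbitrary sequence of tags
#' (strings or numbers) into a new seed in `[0, 2^31 - 2]`.  Every function in
#' the package that needs more than one independent stream of randomness
#' derives its streams this way, so a whole experiment is a pure function of
#' one master seed while, e.g., the parameter-selection stage of two schemes
#' can share a stream and their testing stages cannot.
#'
#' @param seed integer base seed.
#' @param ... tags (coerced with `as.character`) identifying the substream.
#' @return an integer seed suitable for [set.seed()].
#' @examples
#' mix_seed(1, "split")
#' mix_seed(1, "perm", 17)
#' @export
mix_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, prime; keeps h exactly representable in double
  h <- abs(as.double(seed)) %% m
  for (part in unlist(lapply(list(...), as.character))) {
    for (b in utf8ToInt(part)) h <- (h * 31 + b) %% m
  }
  as.integer(h)
}

# Run code under a local RNG state; the caller's .Random.seed is untouched.
local_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}
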