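# Deterministic seed derivation so that every stochastic operation draws
# from its own stream: results cannot change when unrelated code consumes
# random numbers, and a single integer seed reproduces a whole analysis.

#' Derive a substream seed from a master seed and a label
#'
#' A small multiplicative hash mapping (seed, label) pairs to seeds in
#' `[1, 2^31 - 2]`. Used throughout the simulator and bootstrap so module
#' order cannot change results.
#'
#' @param seed integer master seed.
#' @param label character tag naming the consumer (e.g. `"bootstrap"`).
#' @return An integer seed.
#' @export
substream_seed <- function(seed, label) {
  stopifnot(length(seed) == 1, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- as.double(seed %% m)
  for (code in utf8ToInt(as.character(label))) {
    h <- (h * 31 + code) %% m
  }
  h <- (h * 1103515245 + 12345) %% m
  as.integer(h %% (m - 1) + 1)
}

# Evaluate expr with a local RNG state seeded from (seed, label).
with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, label))
  expr
}
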