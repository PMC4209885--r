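#' Derive a reproducible child seed from a master seed and a key path
#'
#' Hierarchical seeding: every stochastic component of a simulated study
#' draws from its own substream, identified by a master seed plus a sequence
#' of string/integer keys (e.g. subject index, stream name). Adding a new
#' stream therefore never perturbs the draws of an existing one. The hash is
#' a plain polynomial rolling hash over the key characters, kept below 2^31
#' so it is a valid R seed on every platform.
#'
#' @param seed master seed (single integer-valued number).
#' @param ... keys (strings or numbers) identifying the substream.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(42, "subject", 3, "semg")
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  keys <- paste(vapply(list(...), function(k) paste(format(k), collapse = "_"),
                       character(1)), collapse = "/")
  m <- 2147483647  # 2^31 - 1, prime
  h <- seed %% m
  for (code in utf8ToInt(keys)) {
    # h <- (h * 131 + code) mod m, exact in doubles since h*131 < 2^31*131 < 2^53
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; restores the
# caller's RNG so simulation never disturbs user-level randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
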