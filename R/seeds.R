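# Seed plumbing: a single master seed fans out to named sub-streams so that
# each stage (cohort, per-subject volumes, folds, training, permutations) is
# independently re-runnable with identical results.

#' Derive a reproducible sub-seed from a master seed and a key
#'
#' A small polynomial string hash (mod a Mersenne-ish prime below 2^31) mixes
#' the master seed with a character key, giving stable per-stage and
#' per-subject seeds independent of the order in which they are drawn.
#'
#' @param seed integer master seed.
#' @param key character key naming the stream (e.g. a subject id).
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(key) == 1L)
  p <- 2147483629
  h <- as.numeric(seed) %% p
  for (code in utf8ToInt(as.character(key))) {
    # doubles stay exact: h < 2^31, h*31 + code < 2^36 < 2^53
    h <- (h * 31 + code) %% p
  }
  as.integer(h)
}

# Run code under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}
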