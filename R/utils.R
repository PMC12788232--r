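# Internal helpers: seeded evaluation and deterministic seed fan-out.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards. Keeps library code from clobbering user RNG.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Derive a child seed from a parent seed and an index path
#'
#' Fans a single global seed out into reproducible per-stage / per-subject /
#' per-trial seeds via a multiplicative congruential hash, so that a subset of
#' the pipeline rerun in isolation draws the same random numbers as the full
#' run. All arithmetic stays exact in double precision and the result lies in
#' `[1, 2^31 - 2]`.
#'
#' @param seed parent integer seed.
#' @param ... integer indices identifying the stage (e.g. subject, protocol,
#'   trial numbers).
#' @return An integer seed.
#' @export
#' @examples
#' childSeed(1, 3, 2, 5)
childSeed <- function(seed, ...) {
  idx <- c(...)
  s <- (as.double(seed) %% 2147483647) + 1
  for (i in idx) s <- (s * 48271 + as.double(i) + 1) %% 2147483647
  as.integer(s + 1)
}

# Cosine similarity between two vectors; 0 for a zero vector.
cosineSim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# All pairwise column cosine similarities of a matrix.
pairwiseCosines <- function(W) {
  k <- ncol(W)
  if (k < 2) return(numeric(0))
  out <- numeric(0)
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    out <- c(out, cosineSim(W[, i], W[, j]))
  out
}

# The normalized-time grid: n points spanning 0..100 percent of the cycle.
timeGrid <- function(n) seq(0, 100, length.out = n)

`%||%` <- function(a, b) if (is.null(a)) b else a
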