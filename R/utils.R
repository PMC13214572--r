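# Seed plumbing: all randomness flows from one experiment seed through named
# substreams so that changing one stage's stream leaves the others untouched.

#' Derive a deterministic sub-seed from a base seed and stream labels
#'
#' Folds the labels into a 31-bit integer with a polynomial string hash and
#' mixes in the base seed, so distinct (seed, label...) combinations map to
#' distinct, reproducible sub-seeds usable with \code{set.seed}.
#'
#' @param seed integer base seed.
#' @param ... stream labels (coerced to character), e.g.
#'   \code{subSeed(1, "noise", "sub03", "run1")}.
#' @return An integer in [1, 2^31 - 2].
#' @export
subSeed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1, keeps exact double arithmetic
  h <- as.numeric(seed) %% m
  for (tok in unlist(lapply(list(...), as.character))) {
    for (b in utf8ToInt(tok)) h <- (h * 31 + b) %% m
    h <- (h * 2654435761) %% m  # Knuth multiplicative scramble between tokens
  }
  as.integer(h %% (m - 1) + 1)
}

# Evaluate expr under a given seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 1-based linear index <-> 1-based (i,j,k) triples for a grid shape
linearToIjk <- function(idx, dm) {
  idx0 <- idx - 1L
  i <- idx0 %% dm[1]
  j <- (idx0 %/% dm[1]) %% dm[2]
  k <- idx0 %/% (dm[1] * dm[2])
  cbind(i + 1L, j + 1L, k + 1L)
}

ijkToLinear <- function(ijk, dm) {
  ijk <- rbind(ijk)
  as.integer((ijk[, 1] - 1L) + (ijk[, 2] - 1L) * dm[1] +
               (ijk[, 3] - 1L) * dm[1] * dm[2] + 1L)
}
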