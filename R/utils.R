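# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL means: use the current RNG stream (no save/restore).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# |i - j| in bins for an n x n grid.
bin_distance_matrix <- function(n) {
  idx <- seq_len(n)
  abs(outer(idx, idx, "-"))
}

is_whole <- function(x, tol = 1e-8) {
  all(abs(x - round(x)) <= tol)
}
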