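# Internal helpers shared across modules.

# Floor used for every division/log guard in the feature battery.
.EPS <- 1e-12
# Cap applied where an entropy would be infinite (no template matches,
# degenerate variance).
.ENTROPY_CAP <- log(1e6)

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-unit seed derived from a master seed, kept within the
# 32-bit integer range R requires.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 100003 + as.double(index) * 7919) %% 2147483629L)
}

# Stratified fold assignment: within each class, units are dealt round-robin
# after a seeded shuffle, so every fold sees both classes whenever possible.
stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a
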