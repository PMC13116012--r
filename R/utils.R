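# Shared internal helpers: seeded evaluation, fold construction, seed fan-out.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream. Used everywhere a documented `seed` argument appears.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Stratified k-fold assignment: within each class, shuffle and deal
# round-robin so fold class counts differ by at most one. Uses the ambient
# RNG stream (callers seed it).
make_stratified_folds <- function(y, k) {
  y <- as.factor(y)
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Counter-based seed fan-out: one global seed deterministically yields an
# independent sub-seed per named stage, so stages can be re-run in isolation.
# Kept strictly below 2^31 (R integers are 32-bit).
stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(global_seed) * 48271 + h) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
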