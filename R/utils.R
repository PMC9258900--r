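# Internal helpers shared across modules.

# Seed the RNG for the calling function's scope, restoring the previous
# state when the caller exits.  Every stochastic operation in the package
# routes through this so results are reproducible given a seed.
local_rng <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  defer_expr <- bquote(assign(".Random.seed", .(old), envir = globalenv()))
  do.call(on.exit, list(defer_expr, add = TRUE), envir = env)
  set.seed(seed)
  invisible(NULL)
}

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise stable softmax of a matrix of logits.
row_softmax <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
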