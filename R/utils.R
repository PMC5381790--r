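# internal helpers shared across modules

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. seed = NULL leaves the current stream untouched.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# flatten a p x k configuration to a length-pk vector (column-major, i.e.
# all x coordinates, then all y, then all z)
vec_config <- function(X) as.vector(X)

unvec_config <- function(v, p, k) matrix(v, nrow = p, ncol = k)

rms <- function(x) sqrt(mean(x^2))

# permutation p-value, observed included among the draws
perm_pvalue <- function(stat_obs, stat_perm) {
  (sum(stat_perm >= stat_obs - 1e-12) + 1) / (length(stat_perm) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
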