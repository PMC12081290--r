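# internal helpers

# Evaluate expr under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards. seed = NULL leaves the global stream alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer or NULL")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic sub-seed for a pipeline stage, kept inside 32-bit range.
stage_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 97L + as.integer(k) * 1009L) %% 2147483587L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
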