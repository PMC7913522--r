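# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and an index/tag.
# Kept strictly below 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(k)) %% 2147483629)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never disturbs user RNG.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_mriqa <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_mriqa(sprintf("`%s` must be a single finite number", name))
  invisible(x)
}
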