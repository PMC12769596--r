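# Internal helpers shared across modules.

# Derive a reproducible 32-bit substream seed from a master seed and one or two
# stream indices. Arithmetic in doubles stays well below 2^53, result < 2^31.
derive_seed <- function(master, index, index2 = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.double(master) %% m) * 48271 %% m
  s <- (s + as.double(index) * 16807 + as.double(index2) * 69621) %% m
  as.integer(s) + 1L
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
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
  force(expr)
}

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}
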