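# Internal RNG helpers.
#
# All user-facing functions that consume randomness take an explicit integer
# seed; per-subject / per-replicate streams are derived deterministically from
# it so that cohorts are reproducible regardless of iteration order.

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed_ <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic stream seed < 2^31 derived from a master seed and an index.
derive_seed <- function(master, index) {
  m <- 2147483647  # 2^31 - 1
  as.integer((abs(as.numeric(master)) %% m * 48271 + as.numeric(index) * 9973 + 1) %% m)
}

stopifnot_scalar_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    stop(sprintf("'%s' must be a single integer", name), call. = FALSE)
  as.integer(x)
}
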