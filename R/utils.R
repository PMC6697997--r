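# Internal helpers: seeding and small validators.

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
# RNG kind is pinned so results are stable across R sessions.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# Derive a per-lesion seed from a base seed; stays well below 2^31.
derive_seed <- function(base, k) {
  (abs(as.integer(base)) %% 500000L) * 2039L + as.integer(k)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
}
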