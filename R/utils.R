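# Internal helpers shared across modules.

# Run `fun()` under a fixed RNG seed, restoring the caller's RNG state.
run_seeded <- function(seed, fun) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  fun()
}

# Lowess smoother used by every residual / pseudo-observation smooth:
# span 2/3, 3 robustness iterations.
haz_lowess <- function(x, y) {
  stats::lowess(x, y, f = 2 / 3, iter = 3)
}

# Derive a child seed deterministically; kept below 2^31.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}
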