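# Internal helpers shared across the package.

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stop_bad_arg <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x)
}

check_prob <- function(x, name, open_left = TRUE) {
  ok <- length(x) == 1L && is.numeric(x) && is.finite(x) &&
    (if (open_left) x > 0 else x >= 0) && x <= 1
  if (!ok) {
    stop_bad_arg("`", name, "` must be a single number in (",
                 if (open_left) "0" else "[0", ", 1]")
  }
  invisible(x)
}
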