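# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. Mersenne-Twister + Rejection sampling pinned for cross-platform
# reproducibility.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", sample.kind = "Rejection")
  expr
}

stop_mda <- function(..., call. = FALSE) stop(..., call. = call.)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_mda(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    stop_mda(sprintf("`%s` must be in [%s, %s], got %s", name, lower, upper, x))
  }
  invisible(x)
}

# Largest absolute asymmetry of a square matrix.
max_asymmetry <- function(x) max(abs(x - t(x)))

msg_info <- function(fmt, ...) message(sprintf(paste0("INFO: ", fmt), ...))
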