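# internal helpers shared across modules

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library calls never perturb a user's random stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number (reproducibility is mandatory)",
         call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# derive a distinct but reproducible sub-seed (kept within 32-bit range)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(offset)) %% 2147483629)
}

stop_if_not_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  }
  if (positive && x <= 0) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  if (nonneg && x < 0) stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
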