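# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Deterministic per-subject seed from a master seed and an index.
# Kept strictly below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(master_seed, index) {
  m <- 2147483629
  as.integer((as.numeric(master_seed) %% m * 48271 + as.numeric(index) * 9973) %% m) + 1L
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name), call. = FALSE)
  }
}

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  }
}

# Normal variates truncated at zero (inverse-CDF sampling, exact).
rtnorm0 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(max(mean, 0), n))
  lo <- pnorm(0, mean, sd)
  u <- runif(n, lo, 1)
  pmax(qnorm(u, mean, sd), 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
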