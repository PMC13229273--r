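# internal helpers

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All user-facing stochastic operations funnel through this so that a given
# seed argument is reproducible and never disturbs the session RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from a parent seed without consuming more
# than one RNG draw pattern; keeps every derived seed inside 32-bit range.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Sample `n` integer gaps from a discretised normal truncated to [lo, hi].
# Probabilities follow the normal density at the integer support, so the
# distribution is symmetric about `mean` whenever [lo, hi] is.
sample_gaps <- function(n, mean, sd, lo, hi) {
  support <- lo:hi
  probs <- dnorm(support, mean = mean, sd = sd)
  support[sample.int(length(support), n, replace = TRUE, prob = probs)]
}

gap_stats <- function(idx) {
  g <- diff(sort(idx))
  if (length(g) == 0L) {
    return(list(n = 0L, min = NA_real_, max = NA_real_,
                mean = NA_real_, sd = NA_real_))
  }
  list(n = length(g), min = min(g), max = max(g),
       mean = mean(g), sd = if (length(g) > 1L) sd(g) else NA_real_)
}

# symmetric inverse square root of a positive-definite matrix
matrix_inv_sqrt <- function(sigma, tol = 1e-10) {
  e <- eigen(sigma, symmetric = TRUE)
  if (any(e$values <= tol * max(e$values))) {
    abort("covariance matrix is not positive definite")
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}
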