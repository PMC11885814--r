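# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Truncated normal via rejection; truncation bounds are far enough from the
# mean in every profile used here that rejection is cheap.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (n == 0) return(numeric(0))
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  guard <- 0L
  while (length(bad) > 0L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
    guard <- guard + 1L
    if (guard > 10000L) abort("truncated-normal rejection failed to converge")
  }
  x
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s]", name, format(lower), format(upper)))
  }
  invisible(x)
}

# Deterministic sub-seed derivation, kept below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2000L + as.integer(offset) %% 2000L
}
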