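# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream. All exported generators route their randomness
# through this so identical params + seed give identical output.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sample-sd that returns 0 (not NA) for n = 1, matching the group-summary
# contract (a single nucleus has zero spread, not undefined spread).
sd0 <- function(x) {
  if (length(x) < 2L) return(0)
  stats::sd(x)
}

# Uniform random unit vectors in 3D (rows), via normalized Gaussians.
runit3 <- function(n) {
  m <- matrix(stats::rnorm(3L * n), ncol = 3L)
  m / sqrt(rowSums(m^2))
}

stop_ <- function(...) stop(..., call. = FALSE)
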