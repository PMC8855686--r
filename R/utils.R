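# Internal helpers shared across modules.

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream. All seeded entry points funnel through here so that package
# functions are pure functions of their seed arguments.
local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# n i.i.d. uniform draws from {-1, +1}, as integers.
rbipolar <- function(n) {
  2L * (stats::runif(n) < 0.5) - 1L
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}
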