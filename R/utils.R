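# internal helpers shared across modules

# wrap angles (degrees) into [0, period)
wrap_deg <- function(x, period = 360) {
  out <- x %% period
  out[out == period] <- 0
  out
}

# signed minimal circular difference a - b in (-period/2, period/2]
circ_diff_deg <- function(a, b, period = 360) {
  d <- (a - b) %% period
  d[d > period / 2] <- d[d > period / 2] - period
  d
}

deg2rad <- function(x) x * pi / 180

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lower || x > upper)
    stopf("'%s' must be in [%g, %g], got %g", name, lower, upper, x)
  invisible(x)
}

# run expr with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
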