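# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All generators must be pure functions of their arguments, so any RNG use
# inside the package goes through this.
with_rng <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("rng_seed must be a single number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Case-normalized gene symbols: upper case, trimmed, duplicates dropped.
norm_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  unique(x[nzchar(x) & !is.na(x)])
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# sample() without its scalar-x surprise
sample_exact <- function(x, size) {
  if (length(x) == 1L) rep(x, length.out = size) else sample(x, size)
}
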