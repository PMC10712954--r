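#' @keywords internal
"_PACKAGE"

# Run `code` under a temporary RNG state seeded with `seed`; the caller's RNG
# stream is restored afterwards. seed = NULL leaves the global stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed for a named pipeline stage from a master seed,
# kept within the 32-bit integer range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}

# population standard deviation (divide by n, not n - 1)
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
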