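# Internal helpers shared across modules.

# Validation error that names the offending field.
stop_field <- function(field, msg, call. = FALSE) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = call.)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (allow_na && length(x) == 1 && is.na(x)) return(invisible(x))
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (x < lower) stop_field(field, sprintf("must be >= %g", lower))
  if (x > upper) stop_field(field, sprintf("must be <= %g", upper))
  invisible(x)
}

check_count <- function(x, field, lower = 0) {
  check_number(x, field, lower = lower)
  if (x != as.integer(x)) stop_field(field, "must be an integer count")
  invisible(as.integer(x))
}

# Deterministic per-entity substream: one master seed, entity i gets
# seed (master * 69069 + i) mod (2^31 - 1), a documented counter scheme so
# entity streams are independent of how many entities precede them.
substream_seed <- function(master, index) {
  as.integer((as.double(master %% 2147483647L) * 69069 + index) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Mean-preserving lognormal multiplicative noise with coefficient of
# variation cv: x * exp(sd * z - sd^2 / 2), sd^2 = log(1 + cv^2).
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -s^2 / 2, sd = s))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
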