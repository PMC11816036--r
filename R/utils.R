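# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_nv <- function(...) stop(sprintf(...), call. = FALSE)

check_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_nv("'%s' must be TRUE or FALSE", what)
  x
}

check_count <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stop_nv("'%s' must be an integer >= %d", what, min)
  as.integer(x)
}

check_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_nv("'%s' must be a probability in [0, 1]", what)
  as.numeric(x)
}

check_range_pair <- function(x, what) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) ||
      any(x != floor(x)) || x[1] < 1L || x[1] > x[2])
    stop_nv("'%s' must be an integer pair (min, max) with 1 <= min <= max", what)
  as.integer(x)
}

# derive k reproducible sub-seeds from a parent seed without disturbing
# the caller's RNG stream more than once
derive_seeds <- function(seed, k) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

logistic <- function(x) 1 / (1 + exp(-x))

# numerically safe binary cross-entropy
bce <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log1p(-p))
}
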