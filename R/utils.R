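# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Sets the global RNG to `seed`, evaluates `code`, and restores the previous
#' RNG state on exit. With `seed = NULL` the code runs on the current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # materialize .Random.seed
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Euclidean norm
vnorm <- function(x) sqrt(sum(x * x))

# Normalize to unit length; errors on (near-)zero vectors.
unit <- function(x, what = "vector") {
  n <- vnorm(x)
  if (!is.finite(n) || n < 1e-12) {
    stop(sprintf("cannot normalize %s with near-zero norm", what), call. = FALSE)
  }
  x / n
}

# Standard error of the mean.
se_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

stop_arg <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
    stop_arg("`%s` must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_arg("`%s` must be a single number in [0, 1]", name)
  }
  as.numeric(x)
}
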