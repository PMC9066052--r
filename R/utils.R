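#' @useDynLib mitoez, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rpois runif quantile mad median sd ecdf
#' @importFrom utils head tail write.csv read.csv
NULL

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so library code never disturbs user-level reproducibility.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Uniformly distributed unit vector, optionally with |z| bounded (useful for
# placing objects in the equatorial band of a flattened cell).
runit3 <- function(max_abs_z = 1) {
  repeat {
    u <- rnorm(3)
    u <- u / sqrt(sum(u^2))
    if (abs(u[3]) <= max_abs_z) return(u)
  }
}

vnorm <- function(v) sqrt(sum(v^2))

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
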