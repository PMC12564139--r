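#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm runif quantile sd predict rbinom
#' @importFrom utils head tail
NULL

# Derive a reproducible child seed from (base seed, index).
# Kept strictly below 2^31 so it is always a valid R integer seed.
deriveSeed <- function(seed, index) {
  s <- (as.double(seed) * 48271 + as.double(index) * 16807 + 12345) %% 2147483629
  as.integer(s)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483629))
  expr
}

assertScalarNumeric <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
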