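# Internal helpers shared across modules.

#' @useDynLib groovemapper, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef median optimize pnorm qnorm quantile rbinom rnorm
#'   runif sd setNames
#' @importFrom utils read.csv read.table write.csv
NULL

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards.  All generators route their randomness through this so
# that no call mutates global state.
with_seed <- function(seed, expr) {
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
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-stage (or per-replicate) seed from one global seed.  Kept
# below 2^31 - 1 so it is always a valid R integer.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 1000003 * as.numeric(index)) %%
               2147483647)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
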