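#' @useDynLib leafcnn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif
#' @importFrom utils write.csv read.csv
NULL

# Deterministic seed mixing: derive independent sub-seeds from one root seed
# without touching global RNG state. Kept below 2^31 - 1 so set.seed() accepts
# the result; arithmetic stays exact in doubles (< 2^53).
mix_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (k in ks) {
    s <- (s * 48271 + as.numeric(k) * 8191 + 1) %% 2147483647
  }
  as.integer(s)
}

# Evaluate code under a local RNG stream, restoring the caller's state.
with_rng <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_leafcnn <- function(..., stage = NULL) {
  msg <- paste0(...)
  if (!is.null(stage)) msg <- sprintf("[%s] %s", stage, msg)
  stop(msg, call. = FALSE)
}

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == floor(x) && x >= min
}

`%||%` <- function(a, b) if (is.null(a)) b else a
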