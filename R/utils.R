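#' @useDynLib edrhythms, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cor density dist kmeans lm pnorm rbeta rnbinom
#'   rnorm runif sd var quantile coef
#' @importFrom utils read.csv write.csv
NULL

#' Wrap clock hours onto the 24-h circle
#' @param x hours.
#' @return `x` modulo 24, in `[0, 24)`.
#' @export
wrap24 <- function(x) x %% 24

#' Half-open sleep-window membership on the 24-h circle
#'
#' Tests whether clock time `t` lies in `[onset, offset)`; the window may
#' wrap midnight. A time exactly at `offset` is outside.
#'
#' @param t clock hours.
#' @param onset,offset window bounds, clock hours.
#' @return Logical vector.
#' @export
in_sleep_window <- function(t, onset, offset) {
  dur <- wrap24(offset - onset)
  wrap24(t - onset) < dur
}

# Evaluate a block with a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL runs the block under the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds (31-bit positive integers) from a seed.
child_seeds <- function(n, seed = NULL) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
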