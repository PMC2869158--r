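#' @keywords internal
"_PACKAGE"

#' @importFrom stats pchisq pnorm qnorm quantile rbinom rexp rgamma rnorm runif
#'   sd var median lm.fit plogis rlnorm setNames uniroot binom.test aggregate
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a master seed and an index path
#'
#' Deterministic integer hash so that every stochastic sub-task (imputation
#' chain, bootstrap draw, simulation replicate) gets its own reproducible
#' stream addressed by `(master seed, indices...)`.
#'
#' @param seed master seed (integer).
#' @param ... further non-negative integer indices identifying the sub-task.
#' @return a single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  k <- c(seed, ...)
  stopifnot(length(k) >= 1, all(is.finite(k)))
  a <- 0
  for (v in k) a <- (a * 69069 + (as.double(v) %% 2147483647) + 1) %% 2147483647
  as.integer(a)
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(ok, ...) if (!isTRUE(ok)) stop_config(...)

# quantile convention used throughout (empirical quantiles, type 7)
qtl <- function(x, p) unname(quantile(x, p, type = 7, names = FALSE, na.rm = TRUE))
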