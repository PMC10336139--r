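#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rgamma rbeta rbinom rlnorm rnbinom rhyper
#'   rmultinom dnbinom dpois optim sd var cor quantile pnorm dnorm qnorm
#'   wilcox.test p.adjust kmeans dist setNames aggregate rexp median
#' @importFrom utils head tail read.delim write.table
#' @importFrom methods as is
NULL

# Row-wise softmax with max-subtraction overflow guard.
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# log(sum(exp(x))) over an arbitrary numeric object, stabilized.
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a deterministic child seed
#'
#' Hashes a parent seed with any number of string/numeric qualifiers into a
#' stable integer below 2^31, so independent stochastic components of a
#' pipeline can be seeded reproducibly from one master seed.
#'
#' @param seed parent seed.
#' @param ... qualifiers (coerced to character).
#' @return integer seed.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647L
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else as.matrix(x)
}

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}
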