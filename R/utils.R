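#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif sd
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the R random seed for the duration of `code` and restores the
#' caller's generator state afterwards, so that seeded simulations do not
#' perturb the global RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("p300tl_invalid_argument", "error")))
}

assert_that <- function(ok, ...) if (!isTRUE(ok)) stop_invalid(...)

is_count <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x == round(x) && x >= 0

is_scalar <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softplus <- function(x) {
  out <- x
  small <- x < 30
  out[small] <- log1p(exp(x[small]))
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# row-wise log-sum-exp of a matrix
row_logsumexp <- function(a) {
  m <- apply(a, 1L, max)
  m + log(rowSums(exp(a - m)))
}

# subtract a row vector from each row / multiply each row, without sweep()
row_center <- function(x, v) x - rep(v, each = nrow(x))
row_scale <- function(x, v) x * rep(v, each = nrow(x))
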