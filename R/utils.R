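#' @importFrom stats rnorm runif rbinom rpois rlnorm predict
#' @importFrom methods is as new
#' @importFrom Matrix sparseMatrix crossprod t colSums rowSums Diagonal
NULL

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logistic <- function(x) 1 / (1 + exp(-x))

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(sprintf("`%s` must be finite", what), call. = FALSE)
  }
  invisible(x)
}

#' Derive a reproducible sub-seed from a master seed and a label
#'
#' All stochastic stages of the package draw their own seed from one master
#' seed so that, e.g., topology construction and input encoding can be varied
#' independently while the whole experiment stays a pure function of the
#' master seed.
#'
#' @param seed master integer seed.
#' @param label character tag naming the consumer (e.g. `"topology"`).
#' @return an integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  bytes <- utf8ToInt(paste0(label, ":", format(seed, scientific = FALSE)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
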