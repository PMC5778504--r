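#' @useDynLib bubbleFRET, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm rpois rexp runif sd var dnorm optimize
#'   quantile setNames cor pgamma
#' @importFrom utils write.table read.table head tail
NULL

#' Derive a reproducible sub-stream seed
#'
#' Expands a single user-facing seed into independent per-stage /
#' per-molecule seeds via an integer mixing function, so that re-running a
#' single stage (or a single molecule) reproduces exactly the same random
#' numbers as the full pipeline run.
#'
#' @param seed base integer seed.
#' @param ... further integer indices (stage id, molecule index, ...).
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
substream_seed <- function(seed, ...) {
  idx <- c(seed, ...)
  m <- 2147483647            # 2^31 - 1 (prime)
  h <- 104729
  for (k in idx) {
    stopifnot(is.numeric(k), length(k) == 1L, is.finite(k))
    # 64-bit-safe modular mix using doubles (values stay < 2^53)
    h <- ((h * 69069) %% m + (abs(k) %% m) * 2654435 %% m + 1013904223) %% m
  }
  as.integer(h %% (m - 2L) + 1L)
}

# run expr with a local RNG state seeded at `seed`
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
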