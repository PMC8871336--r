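# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's RNG
#' state (including absence of a prior `.Random.seed`). With `seed = NULL`
#' the code runs under the current RNG state unchanged.
#'
#' @param seed Single finite number, or `NULL` for a no-op.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @examples
#' with_seed(1, runif(2))
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# Composite-Simpson nodes and weights on [support[1], support[2]]; n must be odd.
simpson_grid <- function(support, n = 2001L) {
  stopifnot(length(support) == 2L, support[1] < support[2])
  n <- as.integer(n)
  if (n %% 2L == 0L) n <- n + 1L
  x <- seq(support[1], support[2], length.out = n)
  h <- (support[2] - support[1]) / (n - 1L)
  w <- rep(c(2, 4), length.out = n)
  w[c(1L, n)] <- 1
  list(x = x, w = w * h / 3)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop(sprintf("'%s' must be a single non-negative finite number", name),
         call. = FALSE)
  invisible(x)
}

# Deterministic polynomial hash of an R object, for stamping pipeline outputs.
config_hash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2L))
  h <- 0
  for (b in raw) h <- (h * 31 + b) %% 2147483647
  sprintf("%x", h)
}
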