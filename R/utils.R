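#' @importFrom stats rnorm sd var fft coef glm predict binomial dnorm pnorm
#'   qnorm quantile setNames aggregate complete.cases
#' @importFrom utils head tail combn modifyList write.csv read.csv
#' @importFrom graphics hist legend
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so simulation calls do not perturb the
# user's random stream.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic derived seed, kept inside 32-bit integer range.
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.double(master) %% 2147483647
  for (i in idx) s <- (s * 48271 + as.double(i) + 1) %% 2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(name, " must be a finite number", call. = FALSE)
  if (positive && x <= 0)
    stop(name, " must be positive", call. = FALSE)
  invisible(x)
}
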