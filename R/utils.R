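#' @importFrom rlang abort warn %||%
#' @importFrom stats median mad sd cor var setNames complete.cases p.adjust
#'   pt qnorm rnorm runif quantile phyper ks.test t.test prcomp
#' @importFrom utils head modifyList
NULL

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Derive a child seed that stays inside the 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

assert_scalar_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (strict_min && x <= min) {
    abort(sprintf("`%s` must be > %s", name, format(min)))
  }
  if (!strict_min && x < min) {
    abort(sprintf("`%s` must be >= %s", name, format(min)))
  }
  invisible(x)
}

`%||%` <- rlang::`%||%`
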