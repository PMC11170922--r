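#' @importFrom stats anova binomial coef cor dnorm glm integrate lm median
#'   pchisq qchisq pnorm predict qnorm quantile rbinom rexp rnorm runif sd
#'   setNames uniroot vcov complete.cases
#' @importFrom utils head
#' @import data.table
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generators are pure functions of
#' `(arguments, seed)` and never disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_invalid("`seed` must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a sub-seed for a named pipeline stage from a master seed, kept
# within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% .Machine$integer.max)
}

assert_prob <- function(x, name, open = TRUE) {
  bad <- if (open) any(x <= 0 | x >= 1) else any(x < 0 | x > 1)
  if (any(is.na(x)) || bad) {
    stop_invalid("`%s` must lie in %s", name, if (open) "(0, 1)" else "[0, 1]")
  }
  invisible(x)
}
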