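# Internal helpers shared across modules.

#' Evaluate an expression under a fixed RNG seed, restoring global state
#'
#' All stochastic operations in the package take explicit `seed` arguments
#' and route their draws through this helper, so nothing depends on (or
#' clobbers) the caller's global random state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# stopifnot() with a custom message
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# population variance (divide by n, not n-1)
pop_var <- function(x) {
  m <- mean(x)
  mean((x - m)^2)
}
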