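#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the random seed, evaluates `expr`, and restores the caller's RNG
#' state afterwards so that seeded helpers do not disturb the global
#' random stream. A `NULL` seed evaluates `expr` with the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

stop_input <- function(...) stop(..., call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_input(sprintf("'%s' must be a single finite number", name))
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    stop_input(sprintf("'%s' = %g is outside its valid range [%g, %g]",
                       name, x, lower, upper))
  }
  invisible(x)
}
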