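`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "atmcorr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's random-number state afterwards, so seeded helpers do
#' not perturb an enclosing simulation.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
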