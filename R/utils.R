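#' @keywords internal
"_PACKAGE"

#' Inverse-logit transform
#'
#' Maps a real number to the open unit interval.
#'
#' @param x numeric vector on the logit scale.
#' @return numeric vector of probabilities.
#' @export
inv_logit <- function(x) 1 / (1 + exp(-x))

#' Logit transform
#'
#' @param p numeric vector of probabilities in (0, 1).
#' @return numeric vector on the logit scale.
#' @export
logit <- function(p) {
  stopifnot(all(p > 0 & p < 1))
  log(p / (1 - p))
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_sspm <- function(...) stop(..., call. = FALSE)
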