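#' Round half up to a fixed number of decimals
#'
#' Percent values in reports are rounded half-up (so 13.835 -> 13.84), unlike
#' base \code{round()} which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' roundHalfUp(13.835, 2)
#' @export
roundHalfUp <- function(x, digits = 2L) {
  m <- 10^digits
  # add a tiny epsilon relative to x to defuse binary-representation error
  # just below .5 boundaries (e.g. 13.835 stored as 13.8349999...)
  floor(x * m + 0.5 + sign(x) * .Machine$double.eps * abs(x) * m) / m
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs \code{expr} under \code{set.seed(seed)} and restores the caller's
#' RNG state afterwards, so package functions never leak global RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of \code{expr}.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# random DNA of length n over ACGT (uniform unless base probs given)
randomDna <- function(n, prob = NULL) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_int <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %s", name, min))
  invisible(as.integer(x))
}
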