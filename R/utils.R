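# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds it with `seed`, evaluates `expr` and
#' restores the previous state, so seeded routines never disturb the global
#' random stream. A `NULL` seed evaluates `expr` as-is.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Coerce positions to an n x 2 matrix with columns pc1, pc2.
# Accepts a 2-column matrix, a data frame with pc1/pc2 (or x/y) columns,
# or a length-2 numeric vector (a single position).
as_positions <- function(x) {
  if (is.data.frame(x)) {
    nm <- names(x)
    if (all(c("pc1", "pc2") %in% nm)) m <- cbind(x$pc1, x$pc2)
    else if (all(c("x", "y") %in% nm)) m <- cbind(x$x, x$y)
    else if (ncol(x) >= 2) m <- as.matrix(x[, 1:2])
    else stopf("positions need two coordinates (pc1, pc2)")
  } else if (is.matrix(x)) {
    if (ncol(x) < 2) stopf("position matrix needs 2 columns")
    m <- x[, 1:2, drop = FALSE]
  } else if (is.numeric(x) && length(x) == 2) {
    m <- matrix(x, 1, 2)
  } else {
    stopf("cannot interpret positions of class '%s'", class(x)[1])
  }
  m <- matrix(as.numeric(m), nrow = nrow(as.matrix(m)))
  if (!all(is.finite(m))) stopf("positions contain non-finite values")
  colnames(m) <- c("pc1", "pc2")
  m
}

# row-wise maxima of a numeric matrix without extra dependencies
row_max <- function(m) do.call(pmax, as.data.frame(m))
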