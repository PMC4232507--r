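#' Define a box-constrained search space
#'
#' @param lower,upper numeric vectors of equal length giving the box bounds;
#'   every `lower[k]` must be strictly below `upper[k]`.  Scalars are
#'   recycled to `dim`.
#' @param dim problem dimension; defaults to the length of the bounds.
#' @return An object of class `search_space` with fields `dim`, `lower`,
#'   `upper`.
#' @examples
#' search_space(-100, 100, dim = 30)
#' @export
search_space <- function(lower, upper, dim = max(length(lower), length(upper))) {
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (!all(is.finite(lower)) || !all(is.finite(upper)))
    stop("search-space bounds must be finite")
  if (any(lower >= upper))
    stop("every lower bound must be strictly below its upper bound")
  structure(list(dim = dim, lower = lower, upper = upper),
            class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat(sprintf("<search_space> %d-D, [%g, %g] ... [%g, %g]\n", x$dim,
              x$lower[1], x$upper[1], x$lower[x$dim], x$upper[x$dim]))
  invisible(x)
}

#' Clamp a position back into the search box
#'
#' @param x numeric position vector.
#' @param space a [search_space()].
#' @return The repaired position.
#' @export
repair_bounds <- function(x, space) {
  pmin(pmax(x, space$lower), space$upper)
}

# Uniform initial positions, one firefly per row.  Consumes N*D uniform
# draws column by column, matching the compiled engine's expectations.
init_positions <- function(space, n) {
  u <- matrix(runif(n * space$dim), n, space$dim)
  sweep(sweep(u, 2, space$upper - space$lower, "*"), 2, space$lower, "+")
}

#' Initialise an evaluated firefly population
#'
#' @param space a [search_space()].
#' @param n population size.
#' @param objective function mapping a position vector to a scalar; non-finite
#'   values are recorded as `Inf` (the firefly is retained).
#' @return An object of class `firefly_pop`: positions (n x D matrix), their
#'   objective values, the best-so-far record and a generation counter.
#' @export
init_population <- function(space, n, objective) {
  X <- init_positions(space, n)
  v <- apply(X, 1, function(p) {
    y <- objective(p)
    if (!is.finite(y)) Inf else y
  })
  ib <- which.min(v)
  structure(list(positions = X, values = v,
                 best_position = X[ib, ], best_value = v[ib],
                 generation = 0L, evaluations = n),
            class = "firefly_pop")
}

#' @export
print.firefly_pop <- function(x, ...) {
  cat(sprintf("<firefly_pop> n=%d, D=%d, generation %d, best %.6g\n",
              nrow(x$positions), ncol(x$positions), x$generation,
              x$best_value))
  invisible(x)
}
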