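# Registry of the classic twelve benchmark functions (30-D suite used
# throughout the swarm-optimization comparison literature).  Bounds and
# conventional success thresholds follow the cited PSO-comparison lineage;
# f8's threshold is measured from its known optimum -418.9829 * D.
benchmark_registry <- function() {
  data.frame(
    name = paste0("f", 1:12),
    fullname = c("Sphere", "Schwefel 2.22", "Quadric", "Schwefel 2.21",
                 "Rosenbrock", "Step", "Noisy Quartic", "Schwefel 2.26",
                 "Rastrigin", "Ackley", "Griewank", "Penalized 1"),
    lower = c(-100, -10, -100, -100, -10, -100, -1.28, -500, -5.12, -32,
              -600, -50),
    upper = c(100, 10, 100, 100, 10, 100, 1.28, 500, 5.12, 32, 600, 50),
    optimum_per_dim = c(0, 0, 0, 0, 0, 0, 0, -418.9828872724339, 0, 0, 0, 0),
    threshold = c(0.01, 0.01, 100, 1, 100, 1e-9, 0.05, 2569.5, 50, 0.01,
                  0.01, 0.01),
    stochastic = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                   FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Construct a benchmark problem
#'
#' The suite: f1 Sphere, f2 Schwefel 2.22, f3 Quadric, f4 Schwefel 2.21,
#' f5 Rosenbrock, f6 Step, f7 noisy Quartic, f8 Schwefel 2.26, f9
#' Rastrigin, f10 Ackley, f11 Griewank, f12 Penalized-1.  Each problem
#' carries its box bounds, known optimum value and a conventional success
#' threshold; all have a known optimum of 0 except f8, whose optimum is
#' `-418.9829 * dim` at `x = 420.9687`.
#'
#' @param name `"f1"` ... `"f12"`, the function's full name, or an index
#'   1..12.
#' @param dim problem dimension (default 30, the standard comparison
#'   setting).
#' @param threshold success threshold overriding the registry default.
#' @return An object of class `benchmark_problem` with fields `name`,
#'   `fun_id`, `dim`, `space`, `optimum_value`, `success_threshold`.
#' @examples
#' benchmark_problem("f6")
#' benchmark_problem("Ackley", dim = 10)
#' @export
benchmark_problem <- function(name, dim = 30, threshold = NULL) {
  reg <- benchmark_registry()
  idx <- if (is.numeric(name)) as.integer(name)
         else match(name, reg$name, nomatch = match(name, reg$fullname))
  if (is.na(idx) || idx < 1 || idx > 12)
    stop("unknown benchmark function: ", name)
  row <- reg[idx, ]
  structure(list(name = row$name, fullname = row$fullname,
                 fun_id = idx, dim = as.integer(dim),
                 space = search_space(row$lower, row$upper, dim),
                 optimum_value = row$optimum_per_dim * dim,
                 success_threshold = threshold %||% row$threshold,
                 stochastic = row$stochastic),
            class = "benchmark_problem")
}

#' @export
print.benchmark_problem <- function(x, ...) {
  cat(sprintf("<benchmark_problem> %s (%s), %d-D on [%g, %g], optimum %g\n",
              x$name, x$fullname, x$dim, x$space$lower[1], x$space$upper[1],
              x$optimum_value))
  invisible(x)
}

#' The full twelve-function suite
#'
#' @param dim problem dimension applied to every function.
#' @return A named list of [benchmark_problem()] objects `f1` ... `f12`.
#' @export
benchmark_suite <- function(dim = 30) {
  setNames(lapply(1:12, benchmark_problem, dim = dim), paste0("f", 1:12))
}

#' Evaluate a benchmark function
#'
#' @param problem a [benchmark_problem()].
#' @param x position vector of length `problem$dim`.
#' @return The objective value (exact analytic value; f7 adds one uniform
#'   noise draw per call).
#' @export
bench_evaluate <- function(problem, x) {
  if (length(x) != problem$dim)
    stop("position has length ", length(x), ", expected ", problem$dim)
  .bench_eval_cpp(problem$fun_id, as.numeric(x))
}

#' Success rate over a set of trials
#'
#' Fraction of trials whose final best value reaches the accuracy
#' threshold: `value <= threshold` for functions with optimum 0, or
#' `|value - optimum| <= threshold` when `optimum` is supplied (needed for
#' Schwefel 2.26, whose optimum is negative).
#'
#' @param final_values best values, one per trial.
#' @param threshold accuracy threshold.
#' @param optimum known optimum value, or `NULL` to compare raw values.
#' @return A fraction in `[0, 1]`.
#' @export
success_rate <- function(final_values, threshold, optimum = NULL) {
  if (length(final_values) == 0) stop("no trial values given")
  ok <- if (is.null(optimum)) final_values <= threshold
        else abs(final_values - optimum) <= threshold
  mean(ok)
}
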