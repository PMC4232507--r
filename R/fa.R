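#' Euclidean distance between two fireflies
#'
#' @param a,b numeric position vectors of equal length.
#' @return The Euclidean norm of `a - b`.
#' @export
pairwise_distance <- function(a, b) {
  if (length(a) != length(b))
    stop("positions have different dimensions (", length(a), " vs ",
         length(b), ")")
  sqrt(sum((a - b)^2))
}

#' Light intensity seen at distance r
#'
#' `I(r) = I0 * exp(-gamma * r^2)`: the light a firefly emits is absorbed by
#' the medium, so the perceived intensity decreases monotonically with the
#' distance `r` and the absorption coefficient `gamma`.  With `gamma = 0`
#' every firefly sees every other at full intensity (the swarm behaves like
#' a fully-informed PSO); as `gamma -> Inf` no firefly sees any other and
#' the search degenerates to a random walk.
#'
#' @param i0 intensity at `r = 0` (non-negative).
#' @param gamma light absorption coefficient (non-negative).
#' @param r distance (non-negative).
#' @return The attenuated intensity.
#' @export
light_intensity <- function(i0, gamma, r) {
  stopifnot(i0 >= 0, gamma >= 0)
  if (any(r < 0)) stop("distance r must be non-negative")
  i0 * exp(-gamma * r^2)
}

#' Attractiveness at distance r
#'
#' `beta(r) = beta0 * exp(-gamma * r^2)`, the pull a brighter firefly exerts
#' at distance `r`; `beta0` is the attractiveness at zero distance.
#'
#' @param beta0 attractiveness at `r = 0` (positive).
#' @param gamma light absorption coefficient (non-negative).
#' @param r distance (non-negative).
#' @return A value in `(0, beta0]`.
#' @export
attractiveness <- function(beta0, gamma, r) {
  stopifnot(beta0 > 0, gamma >= 0)
  if (any(r < 0)) stop("distance r must be non-negative")
  beta0 * exp(-gamma * r^2)
}

#' Configuration for the standard firefly algorithm
#'
#' @param beta0 attractiveness at zero distance.
#' @param gamma light absorption coefficient, applied to the squared
#'   distance after normalization by `length_scale`.
#' @param alpha0 randomization parameter in [0, 1]; decays linearly to zero
#'   over the run (schedule S0).
#' @param pop_size number of fireflies.
#' @param max_gen number of generations.
#' @param scale_by_range if `TRUE`, the random step in each dimension is
#'   additionally scaled by the box width of that dimension.
#' @param length_scale distance normalization used inside the attraction
#'   exponent; `NULL` (default) means `mean(upper - lower) * sqrt(D)`, which
#'   makes `gamma = 1` usable across domains of any size.
#' @param seed optional integer seed stored with the config; `run_fa()` and
#'   friends use it when no explicit seed is passed.
#' @return An object of class `fa_config`.
#' @export
fa_config <- function(beta0 = 1, gamma = 1, alpha0 = 0.5, pop_size = 40,
                      max_gen = 1000, scale_by_range = FALSE,
                      length_scale = NULL, seed = NULL) {
  stopifnot(is.finite(beta0), beta0 > 0, is.finite(gamma), gamma >= 0,
            is.finite(alpha0), alpha0 >= 0, alpha0 <= 1,
            pop_size >= 1, max_gen >= 1)
  structure(list(beta0 = beta0, gamma = gamma, alpha0 = alpha0,
                 pop_size = as.integer(pop_size),
                 max_gen = as.integer(max_gen),
                 scale_by_range = scale_by_range,
                 length_scale = length_scale, seed = seed),
            class = "fa_config")
}

# Resolve the distance normalization for a space.
resolve_length_scale <- function(cfg, space) {
  if (!is.null(cfg$length_scale)) return(cfg$length_scale)
  mean(space$upper - space$lower) * sqrt(space$dim)
}

#' Move one firefly toward a brighter one
#'
#' Applies the standard position update: an attraction step of size
#' `attractiveness(beta0, gamma, r / length_scale)` along `xj - xi`, plus a
#' randomization step `alpha * rnorm(D)` (optionally scaled per dimension
#' by the box width).  The result is clamped into the search box.
#'
#' @param xi position of the moving (dimmer) firefly.
#' @param xj position of the brighter firefly.
#' @param space a [search_space()].
#' @param cfg an [fa_config()].
#' @param alpha randomization parameter for this move; defaults to
#'   `cfg$alpha0`.
#' @return The new (repaired) position of firefly i.
#' @export
fa_move <- function(xi, xj, space, cfg, alpha = cfg$alpha0) {
  L <- resolve_length_scale(cfg, space)
  r <- pairwise_distance(xi, xj) / L
  beta <- attractiveness(cfg$beta0, cfg$gamma, r)
  scale <- if (isTRUE(cfg$scale_by_range)) space$upper - space$lower else 1
  repair_bounds(xi + beta * (xj - xi) + alpha * rnorm(length(xi)) * scale,
                space)
}

#' One generation of the standard firefly sweep (reference implementation)
#'
#' Pure-R double loop over the population: every firefly is compared with
#' every other and moves toward each brighter one in place, with the
#' objective refreshed after each move; a firefly with no brighter peer
#' takes only the randomization step.  The best-so-far record is updated at
#' the end of the sweep.  This is the readable reference for the compiled
#' engine; both consume random draws in the same order, so their runs are
#' bitwise identical under a common seed.
#'
#' @param pop a `firefly_pop` from [init_population()].
#' @param space a [search_space()].
#' @param cfg an [fa_config()].
#' @param objective objective function (minimized).
#' @return The updated population, generation counter incremented.
#' @export
fa_iterate <- function(pop, space, cfg, objective) {
  N <- nrow(pop$positions); D <- space$dim
  t <- pop$generation + 1L
  a_t <- cfg$alpha0 * (1 - t / cfg$max_gen)
  L <- resolve_length_scale(cfg, space)
  scale <- if (isTRUE(cfg$scale_by_range)) space$upper - space$lower else rep(1, D)
  X <- pop$positions; val <- pop$values; ev <- 0L
  feval <- function(p) { y <- objective(p); if (is.finite(y)) y else Inf }
  for (i in seq_len(N)) {
    any_brighter <- FALSE
    for (j in seq_len(N)) {
      if (val[j] < val[i]) {
        any_brighter <- TRUE
        r <- sqrt(sum((X[i, ] - X[j, ])^2)) / L
        beta <- cfg$beta0 * exp(-cfg$gamma * r^2)
        X[i, ] <- pmin(pmax(X[i, ] + beta * (X[j, ] - X[i, ]) +
                              a_t * rnorm(D) * scale,
                            space$lower), space$upper)
        val[i] <- feval(X[i, ]); ev <- ev + 1L
      }
    }
    if (!any_brighter) {
      X[i, ] <- pmin(pmax(X[i, ] + a_t * rnorm(D) * scale,
                          space$lower), space$upper)
      val[i] <- feval(X[i, ]); ev <- ev + 1L
    }
  }
  bp <- pop$best_position; bv <- pop$best_value
  for (i in seq_len(N)) {
    val[i] <- feval(X[i, ]); ev <- ev + 1L
    if (val[i] < bv) { bv <- val[i]; bp <- X[i, ] }
  }
  pop$positions <- X; pop$values <- val
  pop$best_position <- bp; pop$best_value <- bv
  pop$generation <- t
  pop$evaluations <- pop$evaluations + ev
  pop
}

# Shared driver: run either engine on a problem.  `problem` is a
# benchmark_problem (compiled objective) or a list with fields `objective`
# and `space`.
run_swarm <- function(problem, cfg, seed, adaptive, engine, trace = TRUE) {
  space <- problem$space
  objective <- problem_objective(problem)
  if (!is.null(seed)) set.seed(seed)
  ctrl <- engine_ctrl(cfg, space, adaptive, trace)
  X0 <- init_positions(space, cfg$pop_size)
  if (identical(engine, "cpp")) {
    fun_id <- if (!is.null(problem$fun_id)) problem$fun_id else 0L
    if (fun_id == 0L) ctrl$objective <- objective
    res <- .run_swarm_cpp(X0, fun_id, space$lower, space$upper, ctrl)
  } else {
    v <- apply(X0, 1, function(p) { y <- objective(p); if (is.finite(y)) y else Inf })
    ib <- which.min(v)
    pop <- structure(list(positions = X0, values = v, best_position = X0[ib, ],
                          best_value = v[ib], generation = 0L,
                          evaluations = length(v)),
                     class = "firefly_pop")
    tr <- numeric(cfg$max_gen)
    step <- if (adaptive) adafa_iterate else fa_iterate
    for (t in seq_len(cfg$max_gen)) {
      pop <- step(pop, space, cfg, objective)
      tr[t] <- pop$best_value
    }
    res <- list(best_value = pop$best_value, best_position = pop$best_position,
                trace = tr, evaluations = pop$evaluations)
  }
  structure(list(best_value = res$best_value,
                 best_position = as.numeric(res$best_position),
                 trace = as.numeric(res$trace),
                 evaluations = as.numeric(res$evaluations),
                 problem = problem$name %||% "custom",
                 algorithm = if (adaptive) paste0("AdaFa-", cfg$strategy) else "FA",
                 seed = seed),
            class = "fa_trial")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

problem_objective <- function(problem) {
  if (!is.null(problem$objective)) return(problem$objective)
  fid <- problem$fun_id
  function(x) .bench_eval_cpp(fid, x)
}

engine_ctrl <- function(cfg, space, adaptive, trace) {
  list(max_gen = cfg$max_gen, adaptive = adaptive,
       beta0 = cfg$beta0, gamma = cfg$gamma, alpha0 = cfg$alpha0,
       strategy = strategy_index(cfg$strategy %||% "S0"),
       alpha_c = cfg$alpha_c %||% 1, c_decay = cfg$c_decay %||% 4,
       k_power = cfg$k_power %||% 0.5, delta = cfg$delta %||% 1.5,
       lambda = cfg$lambda %||% 0.1, rho = cfg$rho %||% 0.5,
       g_min = cfg$g_min %||% 0.2, g_max = cfg$g_max %||% 0.8,
       alpha_min = cfg$alpha_min %||% 0, alpha_max = cfg$alpha_max %||% Inf,
       branch_prob = cfg$branch_prob %||% 0.5,
       damp_power = cfg$damp_power %||% 3,
       scale_by_range = isTRUE(cfg$scale_by_range),
       length_scale = resolve_length_scale(cfg, space),
       trace = trace)
}

#' Run the standard firefly algorithm on a problem
#'
#' @param problem a [benchmark_problem()] or a list with fields `objective`
#'   (function) and `space` ([search_space()]).
#' @param cfg an [fa_config()].
#' @param seed integer seed; defaults to `cfg$seed`.
#' @param engine `"cpp"` (compiled, default) or `"r"` (pure-R reference);
#'   both produce identical results for a given seed.
#' @param trace keep the best-so-far value per generation.
#' @return An object of class `fa_trial` with `best_value`, `best_position`,
#'   `trace` (length `max_gen`, non-increasing) and `evaluations`.
#' @examples
#' p <- benchmark_problem("f1", dim = 2)
#' r <- run_fa(p, fa_config(pop_size = 15, max_gen = 50), seed = 1)
#' r$best_value
#' @export
run_fa <- function(problem, cfg = fa_config(), seed = cfg$seed,
                   engine = c("cpp", "r"), trace = TRUE) {
  engine <- match.arg(engine)
  run_swarm(problem, cfg, seed, adaptive = FALSE, engine = engine,
            trace = trace)
}

#' @export
print.fa_trial <- function(x, ...) {
  cat(sprintf("<fa_trial> %s on %s: best %.6g after %d evaluations\n",
              x$algorithm, x$problem, x$best_value, as.integer(x$evaluations)))
  invisible(x)
}
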