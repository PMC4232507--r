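#' Configuration for the adaptive firefly algorithm (AdaFa)
#'
#' Extends [fa_config()] with the adaptive-control parameters: the
#' distance-driven absorption coefficient (amplitude factor `delta`,
#' contraction index `lambda`), the gray-relational diversity control
#' (`rho`, `omega`, bounds `g_min`/`g_max`), the randomization-parameter
#' schedule (`strategy` S0--S5 with constants `alpha_c`, `c_decay`,
#' `k_power` and clamp bounds `alpha_min`/`alpha_max`), the probability of
#' the attraction rule in the heterogeneous update (`branch_prob`) and the
#' decay power of the absolute randomization component (`damp_power`).
#'
#' @inheritParams fa_config
#' @param delta amplitude factor of the adaptive absorption coefficient
#'   (positive); larger values lower the coefficient.
#' @param lambda contraction index (positive); larger values lower the
#'   coefficient, and `lambda = 0` would collapse it to the constant
#'   `1/delta`.
#' @param rho gray distinguishing constant in (0, 1).
#' @param omega per-dimension weights of the gray relational grade; `NULL`
#'   means uniform `1/D`.  Must sum to 1.
#' @param g_min,g_max bounds of the gray coefficient (`g_min < g_max`).
#' @param strategy one of `"S0"` ... `"S5"` selecting the decay schedule of
#'   the randomization parameter.
#' @param alpha_c user constant scaling schedules S1--S3.
#' @param c_decay decay-rate constant of schedules S1--S3.
#' @param k_power power of the population size in schedule S4.
#' @param alpha_min,alpha_max clamp bounds applied to the scheduled
#'   randomization parameter before it scales the random draw.
#' @param branch_prob probability of drawing the attraction rule (rule 1)
#'   for a move; the diversification rule (rule 2) is drawn otherwise.
#' @param damp_power power `p` of the `(1 - t/T)^p` factor damping the
#'   absolute randomization component over the run.
#' @return An object of class `c("adafa_config", "fa_config")`.
#' @export
adafa_config <- function(beta0 = 1, gamma = 1, alpha0 = 0.5, pop_size = 40,
                         max_gen = 1000, scale_by_range = FALSE,
                         length_scale = NULL, seed = NULL,
                         delta = 1.5, lambda = 0.1, rho = 0.5, omega = NULL,
                         g_min = 0.2, g_max = 0.8, strategy = "S1",
                         alpha_c = 1, c_decay = 4, k_power = 0.5,
                         alpha_min = 0, alpha_max = Inf,
                         branch_prob = 0.5, damp_power = 3) {
  cfg <- fa_config(beta0, gamma, alpha0, pop_size, max_gen, scale_by_range,
                   length_scale, seed)
  stopifnot(delta > 0, lambda > 0, rho > 0, rho < 1, g_min <= g_max,
            alpha_min <= alpha_max, branch_prob >= 0, branch_prob <= 1,
            damp_power >= 0)
  strategy <- match.arg(strategy, paste0("S", 0:5))
  if (!is.null(omega)) {
    if (abs(sum(omega) - 1) > 1e-8 || any(omega < 0))
      stop("omega must be non-negative weights summing to 1")
  }
  cfg[c("delta", "lambda", "rho", "omega", "g_min", "g_max", "strategy",
        "alpha_c", "c_decay", "k_power", "alpha_min", "alpha_max",
        "branch_prob", "damp_power")] <-
    list(delta, lambda, rho, omega, g_min, g_max, strategy, alpha_c,
         c_decay, k_power, alpha_min, alpha_max, branch_prob, damp_power)
  class(cfg) <- c("adafa_config", "fa_config")
  cfg
}

strategy_index <- function(strategy) {
  as.integer(sub("^S", "", strategy))
}

#' Mean distance from one firefly to all others
#'
#' @param i index of the firefly.
#' @param positions matrix of positions, one firefly per row.
#' @return `mean(||x_i - x_j||)` over `j != i`.
#' @export
mean_distance <- function(i, positions) {
  n <- nrow(positions)
  if (n < 2) stop("mean distance needs at least two fireflies")
  d <- sqrt(colSums((t(positions[-i, , drop = FALSE]) - positions[i, ])^2))
  sum(d) / (n - 1)
}

#' Distance state of the swarm relative to the best solution
#'
#' For each firefly, its distance to the best-so-far position `d_best`
#' together with the swarm-wide minimum and maximum of those distances, the
#' mean inter-firefly distances (a spread diagnostic) and the normalized
#' distance ratio driving the adaptive absorption coefficient.
#'
#' @param positions matrix of positions, one firefly per row.
#' @param best_position the best-so-far position (the reference point).
#' @return A list with `mean_dist`, `d_best`, `d_min`, `d_max`, `ratio`.
#' @export
distance_state <- function(positions, best_position) {
  n <- nrow(positions)
  d_best <- sqrt(colSums((t(positions) - best_position)^2))
  d_min <- min(d_best); d_max <- max(d_best)
  ratio <- if (d_max > d_min) (d_best - d_min) / (d_max - d_min)
           else rep(0, n)
  md <- if (n >= 2) vapply(seq_len(n), mean_distance, numeric(1),
                           positions = positions) else rep(0, n)
  list(mean_dist = md, d_best = d_best, d_min = d_min, d_max = d_max,
       ratio = ratio)
}

#' Distance ratio of one firefly
#'
#' `(d_best_i - d_min) / (d_max - d_min)`: 0 for the firefly closest to the
#' best solution, 1 for the farthest; defined as 0 for a fully collapsed
#' swarm (`d_max == d_min`).
#'
#' @param state a list from [distance_state()].
#' @param i firefly index.
#' @return A value in `[0, 1]`.
#' @export
distance_ratio <- function(state, i) {
  if (state$d_max <= state$d_min) return(0)
  (state$d_best[i] - state$d_min) / (state$d_max - state$d_min)
}

#' Distance-adaptive light absorption coefficient
#'
#' `gamma_i = exp(-lambda * ratio_i) / delta`.  The coefficient decreases in
#' both the amplitude factor `delta` and the contraction index `lambda`,
#' grows sharply when both are small, and collapses to the constant
#' `1/delta` when the effect of `lambda` is removed.  Fireflies far from
#' the best solution (ratio near 1) get a smaller coefficient, hence see
#' farther and are pulled more strongly back toward the swarm.
#'
#' @param ratio distance ratio in `[0, 1]` (see [distance_ratio()]).
#' @param delta amplitude factor (positive).
#' @param lambda contraction index (positive).
#' @return A positive coefficient.
#' @export
adaptive_gamma <- function(ratio, delta, lambda) {
  if (any(delta <= 0) || any(lambda <= 0))
    stop("delta and lambda must be positive")
  exp(-lambda * ratio) / delta
}

#' Attractiveness with a per-firefly absorption coefficient
#'
#' Identical to [attractiveness()] but with the adaptive `gamma_i` of
#' [adaptive_gamma()] in place of the global constant.
#'
#' @param beta0 attractiveness at zero distance.
#' @param gamma_i per-firefly absorption coefficient.
#' @param r distance (non-negative).
#' @return A value in `(0, beta0]`.
#' @export
adaptive_attractiveness <- function(beta0, gamma_i, r) {
  attractiveness(beta0, gamma_i, r)
}

#' Gray relational coefficient per dimension
#'
#' The Deng coefficient between a reference sequence and a comparative
#' sequence: `(dmin + rho*dmax) / (|ref_k - cmp_k| + rho*dmax)`, where
#' `dmin`/`dmax` are the global minimum/maximum absolute deviations over
#' all comparative sequences and dimensions.  Equals 1 exactly where the
#' deviation attains the global minimum; if all deviations are equal the
#' coefficient is 1 everywhere.
#'
#' @param ref reference sequence (the best firefly's position).
#' @param cmp comparative sequence (a firefly's position).
#' @param rho distinguishing constant in (0, 1).
#' @param delta_min,delta_max global min/max absolute deviation over the
#'   whole population; computed from `ref` and `cmp` alone if missing.
#' @param k optional dimension index; default returns all dimensions.
#' @return Coefficients in `(0, 1]`.
#' @export
gray_relational_coefficient <- function(ref, cmp, rho = 0.5,
                                        delta_min = NULL, delta_max = NULL,
                                        k = NULL) {
  stopifnot(rho > 0, rho < 1)
  dev <- abs(ref - cmp)
  if (is.null(delta_min)) delta_min <- min(dev)
  if (is.null(delta_max)) delta_max <- max(dev)
  out <- if (delta_max <= 0) rep(1, length(dev))
         else (delta_min + rho * delta_max) / (dev + rho * delta_max)
  if (is.null(k)) out else out[k]
}

#' Gray relational grade
#'
#' Weighted combination of the per-dimension coefficients; equals 1 iff all
#' coefficients are 1 (the sequences coincide at the global-minimum
#' deviation everywhere).
#'
#' @param coefficients per-dimension gray relational coefficients.
#' @param omega weights summing to 1; `NULL` means uniform.
#' @return A value in `(0, 1]`.
#' @export
gray_relational_grade <- function(coefficients, omega = NULL) {
  D <- length(coefficients)
  if (is.null(omega)) omega <- rep(1 / D, D)
  if (abs(sum(omega) - 1) > 1e-8)
    stop("gray weights must sum to 1")
  sum(omega * coefficients)
}

#' Gray diversity coefficient
#'
#' Maps the gray relational grade into the interval `[g_min, g_max]`:
#' `K = g_max - (g_max - g_min) * grade`.  Fireflies similar to the best
#' solution (grade near 1) receive the small bound and exploit; dissimilar
#' ones receive the large bound and explore.  The bounds guarantee that the
#' randomization never dies out completely nor diverges, so the population
#' converges in finite time.
#'
#' @param grade gray relational grade in `(0, 1]`.
#' @param g_min,g_max coefficient bounds (`g_min <= g_max`).
#' @return A value in `[g_min, g_max]`.
#' @export
gray_coefficient <- function(grade, g_min, g_max) {
  stopifnot(g_min <= g_max)
  pmin(pmax(g_max - (g_max - g_min) * grade, g_min), g_max)
}

# Gray state of a population against the best-so-far reference: per-firefly
# grades and diversity coefficients, with the deltas of the coefficient
# computed once over the whole population (they are population-level by
# definition).
gray_state <- function(positions, best_position, cfg) {
  dev <- abs(sweep(positions, 2, best_position))
  delta_min <- min(dev); delta_max <- max(dev)
  D <- ncol(positions)
  omega <- cfg$omega %||% rep(1 / D, D)
  grades <- apply(positions, 1, function(p) {
    gray_relational_grade(
      gray_relational_coefficient(best_position, p, cfg$rho,
                                  delta_min, delta_max), omega)
  })
  list(grades = grades,
       coefficients = gray_coefficient(grades, cfg$g_min, cfg$g_max))
}

#' Randomization-parameter decay schedules S0--S5
#'
#' S0 is the linear decay of the standard algorithm,
#' `alpha0 * (1 - t/T)`.  S1--S5 decay non-linearly and span a wider range
#' over the run than S0:
#' \describe{
#'   \item{S1}{`alpha_c * exp(-c * t/T)`}
#'   \item{S2}{`alpha_c / (1 + c * t/T)`}
#'   \item{S3}{`alpha_c * exp(-c * (N/D) * t/T)` -- decay rate set by the
#'     ratio of population size to problem dimension}
#'   \item{S4}{`N^(-k * t/T)` -- range grows with both `k` and `N`}
#'   \item{S5}{`N^(1 - t/T) / D` -- trajectories differ with `N` but the
#'     final value `1/D` is independent of the population size}
#' }
#'
#' @param strategy `"S0"` ... `"S5"`.
#' @param t generation, `1 <= t <= max_gen`.
#' @param max_gen total generations `T`.
#' @param pop_size population size `N`.
#' @param dim problem dimension `D`.
#' @param cfg an [adafa_config()] supplying `alpha0`, `alpha_c`, `c_decay`,
#'   `k_power`.
#' @return The scheduled randomization parameter (positive).
#' @export
alpha_schedule <- function(strategy, t, max_gen, pop_size, dim,
                           cfg = adafa_config()) {
  strategy <- match.arg(strategy, paste0("S", 0:5))
  if (any(t < 1) || any(t > max_gen)) stop("t must lie in [1, max_gen]")
  u <- t / max_gen
  switch(strategy,
    S0 = cfg$alpha0 * (1 - u),
    S1 = cfg$alpha_c * exp(-cfg$c_decay * u),
    S2 = cfg$alpha_c / (1 + cfg$c_decay * u),
    S3 = cfg$alpha_c * exp(-cfg$c_decay * u * pop_size / dim),
    S4 = pop_size^(-cfg$k_power * u),
    S5 = pop_size^(1 - u) / dim)
}

#' Randomization term of the adaptive update
#'
#' Clamps the scheduled randomization parameter into
#' `[alpha_min, alpha_max]` and scales a standard-normal draw per
#' dimension, optionally by the box width (`cfg$scale_by_range`).  Zero
#' mean by construction.
#'
#' @param alpha the scheduled randomization parameter.
#' @param cfg an [adafa_config()].
#' @param space a [search_space()].
#' @return A random step vector of length `space$dim`.
#' @export
randomization_term <- function(alpha, cfg, space) {
  a <- min(max(alpha, cfg$alpha_min), cfg$alpha_max)
  scale <- if (isTRUE(cfg$scale_by_range)) space$upper - space$lower else 1
  a * rnorm(space$dim) * scale
}

#' One heterogeneous position update
#'
#' Applies one of the two update laws, drawn uniformly per move
#' (`cfg$branch_prob` for rule 1):
#' \describe{
#'   \item{rule 1 (attraction)}{step toward the brighter firefly with the
#'     distance-adaptive attractiveness, plus the gray-scaled, time-damped
#'     absolute randomization term;}
#'   \item{rule 2 (diversification)}{no attraction; gray-scaled
#'     randomization with both the damped absolute component and a
#'     component scaled by the per-dimension population spread.}
#' }
#' The result is repaired into the search box.
#'
#' @param xi position of the moving firefly.
#' @param xj position of the brighter attractor.
#' @param t current generation.
#' @param cfg an [adafa_config()].
#' @param space a [search_space()].
#' @param K gray diversity coefficient of firefly i.
#' @param gamma_i adaptive absorption coefficient of firefly i.
#' @param spread per-dimension population spread (standard deviations).
#' @param rule force rule `1` or `2`; `NULL` draws it at random.
#' @return The new (repaired) position.
#' @export
heterogeneous_update <- function(xi, xj, t, cfg, space, K = 1,
                                 gamma_i = cfg$gamma,
                                 spread = rep(0, space$dim), rule = NULL) {
  a_t <- alpha_schedule(cfg$strategy, t, cfg$max_gen, cfg$pop_size,
                        space$dim, cfg)
  a_eff <- min(max(a_t, cfg$alpha_min), cfg$alpha_max)
  damp <- (1 - t / cfg$max_gen)^cfg$damp_power
  if (is.null(rule)) {
    rule <- if (cfg$branch_prob >= 1) 1
            else if (cfg$branch_prob <= 0) 2
            else if (runif(1) < cfg$branch_prob) 1 else 2
  }
  D <- space$dim
  new <- if (rule == 1) {
    r <- pairwise_distance(xi, xj) / resolve_length_scale(cfg, space)
    beta <- adaptive_attractiveness(cfg$beta0, gamma_i, r)
    xi + beta * (xj - xi) + K * a_eff * damp * rnorm(D)
  } else {
    z <- rnorm(2 * D)
    xi + K * a_eff * (damp * z[seq(1, 2 * D, by = 2)] +
                        spread * z[seq(2, 2 * D, by = 2)])
  }
  repair_bounds(new, space)
}

#' One generation of the adaptive firefly sweep (reference implementation)
#'
#' Recomputes the distance state (adaptive absorption coefficients) and the
#' gray state (diversity coefficients) against the best-so-far position,
#' then runs the double-loop sweep with the heterogeneous update rules and
#' one spread-scaled diversification kick per firefly.  Mirrors the
#' compiled engine draw-for-draw, so both engines agree bitwise under a
#' common seed.
#'
#' @inheritParams fa_iterate
#' @param cfg an [adafa_config()].
#' @return The updated population.
#' @export
adafa_iterate <- function(pop, space, cfg, objective) {
  N <- nrow(pop$positions); D <- space$dim
  t <- pop$generation + 1L
  a_t <- alpha_schedule(cfg$strategy, t, cfg$max_gen, N, D, cfg)
  a_eff <- min(max(a_t, cfg$alpha_min), cfg$alpha_max)
  damp <- (1 - t / cfg$max_gen)^cfg$damp_power
  L <- resolve_length_scale(cfg, space)
  X <- pop$positions; val <- pop$values; ev <- 0L
  feval <- function(p) { y <- objective(p); if (is.finite(y)) y else Inf }

  dstate <- distance_state(X, pop$best_position)
  gam <- adaptive_gamma(dstate$ratio, cfg$delta, cfg$lambda)
  gstate <- gray_state(X, pop$best_position, cfg)
  K <- gstate$coefficients
  spread <- sqrt(colSums(sweep(X, 2, colMeans(X))^2) / (N - 1))

  for (i in seq_len(N)) {
    any_brighter <- FALSE
    for (j in seq_len(N)) {
      if (val[j] < val[i]) {
        any_brighter <- TRUE
        rule <- if (cfg$branch_prob >= 1) 1
                else if (cfg$branch_prob <= 0) 2
                else if (runif(1) < cfg$branch_prob) 1 else 2
        if (rule == 1) {
          r <- sqrt(sum((X[i, ] - X[j, ])^2)) / L
          beta <- cfg$beta0 * exp(-gam[i] * r^2)
          X[i, ] <- X[i, ] + beta * (X[j, ] - X[i, ]) +
            K[i] * a_eff * damp * rnorm(D)
        } else {
          z <- matrix(rnorm(2 * D), nrow = 2)
          X[i, ] <- X[i, ] + K[i] * a_eff * (damp * z[1, ] + spread * z[2, ])
        }
        X[i, ] <- pmin(pmax(X[i, ], space$lower), space$upper)
        val[i] <- feval(X[i, ]); ev <- ev + 1L
      }
    }
    X[i, ] <- pmin(pmax(X[i, ] + K[i] * a_eff * spread * rnorm(D),
                        space$lower), space$upper)
    if (!any_brighter) {
      X[i, ] <- pmin(pmax(X[i, ] + a_eff * damp * rnorm(D),
                          space$lower), space$upper)
    }
    val[i] <- feval(X[i, ]); ev <- ev + 1L
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

#' Run the adaptive firefly algorithm on a problem
#'
#' @inheritParams run_fa
#' @param cfg an [adafa_config()]; `cfg$strategy` selects the
#'   randomization-parameter schedule.
#' @return An object of class `fa_trial`.
#' @examples
#' p <- benchmark_problem("f1", dim = 2)
#' r <- run_adafa(p, adafa_config(pop_size = 15, max_gen = 50), seed = 1)
#' r$best_value
#' @export
run_adafa <- function(problem, cfg = adafa_config(), seed = cfg$seed,
                      engine = c("cpp", "r"), trace = TRUE) {
  engine <- match.arg(engine)
  stopifnot(inherits(cfg, "adafa_config"))
  run_swarm(problem, cfg, seed, adaptive = TRUE, engine = engine,
            trace = trace)
}
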