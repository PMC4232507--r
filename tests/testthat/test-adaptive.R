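test_that("mean distance matches brute-force enumeration and is translation-invariant", {
  X <- rbind(c(0, 0), c(1, 0), c(2, 0))
  expect_equal(mean_distance(2, X), (1 + 1) / 2)
  expect_equal(mean_distance(1, X), (1 + 2) / 2)
  Xsame <- matrix(3, 4, 2)
  expect_equal(mean_distance(1, Xsame), 0)
  set.seed(8)
  Y <- matrix(rnorm(15), 5, 3)
  brute <- mean(vapply((2:5), function(j) sqrt(sum((Y[1, ] - Y[j, ])^2)),
                       numeric(1)))
  expect_equal(mean_distance(1, Y), brute)
  expect_equal(mean_distance(3, sweep(Y, 2, c(5, -2, 7), "+")),
               mean_distance(3, Y))
  expect_error(mean_distance(1, Y[1, , drop = FALSE]), "at least two")
})

test_that("distance ratio attains its extremes and degrades to 0 when collapsed", {
  X <- rbind(c(0, 0), c(1, 0), c(4, 0))
  st <- distance_state(X, best_position = c(0, 0))
  expect_equal(distance_ratio(st, 1), 0)   # closest to the best
  expect_equal(distance_ratio(st, 3), 1)   # farthest
  expect_true(all(st$d_best >= st$d_min & st$d_best <= st$d_max))
  collapsed <- distance_state(matrix(1, 5, 2), best_position = c(1, 1))
  expect_equal(distance_ratio(collapsed, 2), 0)
})

test_that("adaptive absorption coefficient is positive and monotone in delta and lambda", {
  for (ratio in c(0, 0.3, 1)) {
    for (delta in c(0.3, 1, 2.5)) {
      for (lam in c(0.05, 0.5, 2)) {
        g <- adaptive_gamma(ratio, delta, lam)
        expect_gt(g, 0)
        expect_lt(adaptive_gamma(ratio, delta + 1, lam), g)
        if (ratio > 0) expect_lt(adaptive_gamma(ratio, delta, lam + 1), g)
      }
    }
  }
  # large when delta and lambda are both very small
  expect_gt(adaptive_gamma(0.5, 1e-3, 1e-3), 100)
  expect_error(adaptive_gamma(0.5, -1, 0.1), "positive")
  # per-firefly attractiveness: different ratios give different pulls
  g1 <- adaptive_gamma(0.1, 1.5, 0.8); g2 <- adaptive_gamma(0.9, 1.5, 0.8)
  expect_false(adaptive_attractiveness(1, g1, 2) ==
                 adaptive_attractiveness(1, g2, 2))
  expect_equal(adaptive_attractiveness(1, 0.7, 0), 1)
  expect_equal(adaptive_attractiveness(1, 0.7, 1.3),
               attractiveness(1, 0.7, 1.3))
})

test_that("gray relational coefficient follows the Deng formula with its guards", {
  ref <- c(1, 2, 3); cmp <- c(1.5, 2, 2)
  dev <- abs(ref - cmp)                      # 0.5, 0, 1
  rho <- 0.4
  co <- gray_relational_coefficient(ref, cmp, rho)
  expect_equal(co[2], 1)                     # attains the global min delta
  expect_equal(co[3], (0 + rho * 1) / (1 + rho * 1))  # worst dimension
  expect_true(all(co > 0 & co <= 1))
  # identical sequences: guard returns 1 everywhere
  expect_equal(gray_relational_coefficient(ref, ref, 0.5), rep(1, 3))
  # increasing rho never decreases the worst-dimension coefficient
  worst <- vapply(seq(0.1, 0.9, by = 0.1), function(r)
    gray_relational_coefficient(ref, cmp, r)[3], numeric(1))
  expect_true(all(diff(worst) >= 0))
})

test_that("gray relational grade is a weighted mean with symmetry", {
  expect_equal(gray_relational_grade(rep(1, 6)), 1)
  expect_equal(gray_relational_grade(c(1, 0.5), c(0.5, 0.5)), 0.75)
  co <- c(0.9, 0.4, 0.7); w <- c(0.2, 0.3, 0.5)
  perm <- c(3, 1, 2)
  expect_equal(gray_relational_grade(co, w),
               gray_relational_grade(co[perm], w[perm]))
  expect_error(gray_relational_grade(co, c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("gray coefficient maps grades into its bounds", {
  expect_equal(gray_coefficient(1, 0.2, 0.8), 0.2)   # grade 1 -> lower bound
  for (g in seq(0.05, 1, by = 0.05)) {
    K <- gray_coefficient(g, 0.2, 0.8)
    expect_gte(K, 0.2); expect_lte(K, 0.8)
  }
  expect_equal(gray_coefficient(0.37, 0.5, 0.5), 0.5)  # degenerate bounds
})

test_that("alpha schedules decay, S0 is affine, and S1-S5 span wider ranges", {
  cfg <- adafa_config()
  T <- 1000; N <- 40; D <- 30
  tt <- 1:T
  a0 <- alpha_schedule("S0", tt, T, N, D, cfg)
  expect_lt(max(abs(diff(diff(a0)))), 1e-12)           # affine in t
  range0 <- max(a0) - min(a0)
  for (s in paste0("S", 1:5)) {
    a <- alpha_schedule(s, tt, T, N, D, cfg)
    expect_lte(a[T], a[1])                             # decay contract
    expect_true(all(diff(a) <= 1e-12))
    expect_gt(max(a) - min(a), range0)                 # wider than S0
  }
  # S5 endpoint is independent of the population size
  finals <- vapply(c(20, 40, 80), function(n)
    alpha_schedule("S5", T, T, n, D, cfg), numeric(1))
  expect_lt(max(finals) / min(finals), 1.1)
  expect_error(alpha_schedule("S9", 1, 10, 5, 2, cfg))
  expect_error(alpha_schedule("S1", 0, 10, 5, 2, cfg), "must lie")
  # R schedule matches the compiled one everywhere
  for (s in 0:5) {
    for (t in c(1, 250, 999, 1000)) {
      expect_identical(
        alpha_schedule(paste0("S", s), t, T, N, D, cfg),
        adafa:::.alpha_schedule_cpp(s, t, T, N, D, cfg$alpha0, cfg$alpha_c,
                                    cfg$c_decay, cfg$k_power))
    }
  }
})

test_that("randomization term clamps alpha and has zero mean", {
  space <- search_space(-1, 1, dim = 2)
  cfg <- adafa_config(alpha_min = 0.3, alpha_max = 0.6)
  set.seed(1); z1 <- randomization_term(0.01, cfg, space)  # below alpha_min
  set.seed(1); z2 <- 0.3 * rnorm(2)
  expect_equal(z1, z2)
  cfg0 <- adafa_config(alpha_min = 0.2, alpha_max = 0.2)   # zero-width bounds
  set.seed(2); z3 <- randomization_term(0.9, cfg0, space)
  set.seed(2); z4 <- 0.2 * rnorm(2)
  expect_equal(z3, z4)
  set.seed(3)
  draws <- replicate(5000, randomization_term(0.5, adafa_config(), space)[1])
  expect_lt(abs(mean(draws)), 3 * 0.5 / sqrt(5000))
})

test_that("heterogeneous update draws distinct rules and stays in bounds", {
  space <- search_space(-10, 10, dim = 3)
  cfg <- adafa_config(max_gen = 100)
  xi <- c(1, -2, 3); xj <- c(0, 0, 0)
  set.seed(4)
  u1 <- heterogeneous_update(xi, xj, t = 10, cfg, space, K = 0.5,
                             gamma_i = 0.6, spread = c(1, 1, 1), rule = 1)
  set.seed(4)
  u2 <- heterogeneous_update(xi, xj, t = 10, cfg, space, K = 0.5,
                             gamma_i = 0.6, spread = c(1, 1, 1), rule = 2)
  expect_false(isTRUE(all.equal(u1, u2)))
  set.seed(9); a <- heterogeneous_update(xi, xj, 10, cfg, space)
  set.seed(9); b <- heterogeneous_update(xi, xj, 10, cfg, space)
  expect_identical(a, b)
  tight <- search_space(-0.5, 0.5, dim = 3)
  set.seed(2)
  for (k in 1:20) {
    u <- heterogeneous_update(runif(3, -0.5, 0.5), runif(3, -0.5, 0.5),
                              5, cfg, tight, K = 0.8, spread = rep(2, 3))
    expect_true(all(u >= -0.5 & u <= 0.5))
  }
})

test_that("adaptive engines agree bitwise across strategies", {
  for (s in c("S1", "S4")) {
    p <- benchmark_problem("f9", dim = 6)
    cfg <- adafa_config(pop_size = 7, max_gen = 40, strategy = s)
    rc <- run_adafa(p, cfg, seed = 11, engine = "cpp")
    rr <- run_adafa(p, cfg, seed = 11, engine = "r")
    expect_identical(rc$trace, rr$trace)
    expect_identical(rc$best_position, rr$best_position)
  }
})

test_that("adafa sweep keeps the best-so-far monotone and respects the budget", {
  p <- benchmark_problem("f10", dim = 8)
  cfg <- adafa_config(pop_size = 10, max_gen = 80, strategy = "S2")
  r <- run_adafa(p, cfg, seed = 6)
  expect_length(r$trace, 80)
  expect_true(all(diff(r$trace) <= 0))
  r2 <- run_adafa(p, cfg, seed = 6)
  expect_identical(r$trace, r2$trace)
})

test_that("with collapsed adaptive parameters the sweep behaves like standard FA", {
  # gray bounds pinned to 1, one update rule, no damping, near-constant
  # absorption: both optimizers solve the same small sphere to high accuracy
  p <- benchmark_problem("f1", dim = 5)
  cfg_fa <- fa_config(pop_size = 15, max_gen = 150)
  cfg_ada <- adafa_config(pop_size = 15, max_gen = 150, strategy = "S0",
                          g_min = 1, g_max = 1, branch_prob = 1,
                          damp_power = 0, delta = 1, lambda = 1e-6)
  v_fa <- run_fa(p, cfg_fa, seed = 3)$best_value
  v_ada <- run_adafa(p, cfg_ada, seed = 3)$best_value
  expect_lt(v_fa, 1e-2)
  expect_lt(v_ada, 1e-2)
})

test_that("adafa reaches deep sphere accuracy at the study scale", {
  p <- benchmark_problem("f1", dim = 30)
  cfg <- adafa_config(pop_size = 40, max_gen = 1000, strategy = "S1")
  vals <- vapply(1:3, function(s)
    run_adafa(p, cfg, seed = s, trace = FALSE)$best_value, numeric(1))
  expect_lt(median(vals), 1e-10)
})
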