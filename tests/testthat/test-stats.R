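test_that("block ranking averages ties and conserves the rank sum", {
  m <- results_matrix(rbind(a = 1, b = 2, c = 3))
  expect_equal(as.numeric(rank_blocks(m)), c(1, 2, 3))
  # a six-way tie at the best value shares rank (1+...+6)/6 = 3.5
  m6 <- results_matrix(matrix(c(rep(0, 6), 5, 8, 9), ncol = 1))
  expect_equal(as.numeric(rank_blocks(m6))[1:6], rep(3.5, 6))
  set.seed(4)
  mr <- results_matrix(matrix(rnorm(9 * 12), 9, 12))
  expect_true(all(colSums(rank_blocks(mr)) == 9 * 10 / 2))
})

test_that("Friedman statistic matches independent oracles", {
  # identical columns across algorithms: statistic 0
  m0 <- results_matrix(matrix(rep(c(1, 2, 3), 4), 3, 4, byrow = FALSE))
  m0[] <- 5
  expect_equal(rank_friedman(m0)$statistic, 0)
  # all 3x3 integer tables with entries in {1,2,3} vs the rank-sum formula
  grids <- as.matrix(expand.grid(rep(list(1:3), 9)))
  ours <- vapply(seq_len(nrow(grids)), function(g) {
    tab <- matrix(grids[g, ], 3, 3)
    r <- apply(tab, 2, rank)
    avg <- rowMeans(r)
    12 * 3 / (3 * 4) * sum((avg - 2)^2)
  }, numeric(1))
  # spot-check the vectorized path goes through the exported function
  idx <- seq(1, nrow(grids), by = 397)
  for (g in idx)
    expect_equal(rank_friedman(results_matrix(matrix(grids[g, ], 3, 3)),
                               orientation = "raw")$statistic, ours[g])
  oracle <- vapply(seq_len(nrow(grids)), function(g)
    friedman_ranksum_oracle(matrix(grids[g, ], 3, 3)), numeric(1))
  expect_equal(ours, oracle, tolerance = 1e-12)
  # tie-free tables vs stats::friedman.test (blocks as rows there)
  set.seed(5)
  for (k in 1:20) {
    tab <- matrix(sample(1:60, 24), 4, 6)   # 4 algorithms x 6 blocks
    ours <- rank_friedman(results_matrix(tab), orientation = "raw")$statistic
    ref <- unname(stats::friedman.test(t(tab))$statistic)
    expect_equal(ours, ref, tolerance = 1e-12)
    pv <- rank_friedman(results_matrix(tab), orientation = "raw")$p_value
    expect_equal(pv, unname(stats::friedman.test(t(tab))$p.value),
                 tolerance = 1e-12)
  }
})

test_that("aligned Friedman matches a hand computation and degrades under constancy", {
  # 2x2 toy, computed by hand: scores 1,3 (block 1), 2,8 (block 2)
  tab <- matrix(c(1, 3, 2, 8), 2, 2)
  # aligned: block means 2, 5 -> aligned values -1, 1, -3, 3
  # joint ranks: -3 -> 1, -1 -> 2, 1 -> 3, 3 -> 4
  # Rj (per algorithm): 2 + 1 = 3, 3 + 4 = 7; Ri (per block): 5, 5; M = 4
  Rj <- c(3, 7); Ri <- c(5, 5); n <- 2; N <- 2; M <- 4
  expected <- (n - 1) * (sum(Rj^2) - (n * N^2 / 4) * (M + 1)^2) /
    (M * (M + 1) * (2 * M + 1) / 6 - sum(Ri^2) / n)
  got <- rank_aligned_friedman(results_matrix(tab), orientation = "raw")
  expect_equal(got$statistic, expected)
  expect_equal(unname(sort(got$avg_rank)), sort(Rj / N))
  # constant matrix: all aligned values 0, maximal ties, statistic 0
  cm <- results_matrix(matrix(7, 4, 5))
  got0 <- rank_aligned_friedman(cm, orientation = "raw")
  expect_equal(got0$statistic, 0)
  expect_equal(max(got0$avg_rank) - min(got0$avg_rank), 0)
})

test_that("Quade matches a hand computation and equal ranges mimic Friedman order", {
  tab <- matrix(c(1, 2, 3,
                  2, 6, 4,
                  5, 1, 9), 3, 3)   # 3 algorithms x 3 blocks
  n <- 3; N <- 3
  r <- apply(tab, 2, rank)
  Q <- rank(apply(tab, 2, function(z) diff(range(z))))
  S <- sweep(r, 1, 2) * rep(Q, each = 3)
  Sj <- rowSums(S)
  A2 <- sum(S^2); B <- sum(Sj^2) / N
  expected <- (N - 1) * B / (A2 - B)
  got <- rank_quade(results_matrix(tab), orientation = "raw")
  expect_equal(got$statistic, expected)
  # equal-range blocks: Quade ordering equals the Friedman ordering
  set.seed(6)
  base <- matrix(runif(5 * 4), 5, 4)
  eq <- apply(base, 2, function(col) (col - min(col)) / diff(range(col)))
  fr <- rank_friedman(results_matrix(eq), orientation = "raw")$avg_rank
  qd <- rank_quade(results_matrix(eq), orientation = "raw")$avg_rank
  expect_identical(names(fr), names(qd))
})

test_that("rank invariances hold where the tests depend only on ranks", {
  set.seed(7)
  tab <- matrix(runif(6 * 8, 1, 10), 6, 8)
  m1 <- results_matrix(tab)
  m2 <- results_matrix(tab^3)   # strictly monotone within every block
  f1 <- rank_friedman(m1, orientation = "raw")
  f2 <- rank_friedman(m2, orientation = "raw")
  expect_equal(f1$statistic, f2$statistic)
  expect_equal(f1$avg_rank, f2$avg_rank)
  # aligned Friedman is invariant to per-block shifts (the aligning step)
  shifted <- sweep(tab, 2, runif(8, -50, 50), "+")
  a1 <- rank_aligned_friedman(m1, orientation = "raw")
  a2 <- rank_aligned_friedman(results_matrix(shifted), orientation = "raw")
  expect_equal(a1$statistic, a2$statistic)
})

test_that("the bundled results table is internally consistent under the rank battery", {
  m <- published_benchmark_means()
  expect_equal(dim(m), c(9, 12))
  fr <- rank_friedman(m)
  expect_equal(sum(fr$avg_rank), 45)                 # n(n+1)/2 conservation
  expect_equal(fr$statistic, 1.6 * sum(fr$avg_rank^2) - 360,
               tolerance = 1e-10)
  # both ranking orientations are available and differ only on f8
  rb_err <- rank_blocks(m, orientation = "error")
  rb_raw <- rank_blocks(m, orientation = "raw")
  expect_equal(rb_err[, setdiff(colnames(m), "f8")],
               rb_raw[, setdiff(colnames(m), "f8")])
  expect_false(isTRUE(all.equal(rb_err[, "f8"], rb_raw[, "f8"])))
})

test_that("CPU share normalizes positive times", {
  expect_equal(cpu_share(rep(2, 9)), rep(1 / 9, 9))
  set.seed(8)
  tt <- runif(7, 0.1, 5)
  expect_equal(sum(cpu_share(tt)), 1)
  t2 <- tt; t2[3] <- 2 * t2[3]
  expect_gt(cpu_share(t2)[3], cpu_share(tt)[3])
  expect_error(cpu_share(c(1, 0, 2)), "positive")
})

test_that("results matrices round-trip through CSV", {
  m <- results_matrix(matrix(1:6 / 7, 2, 3,
                             dimnames = list(c("A", "B"), c("f1", "f2", "f3"))),
                      optima = c(0, 0, -5))
  path <- tempfile(fileext = ".csv")
  write_results_matrix(m, path)
  m2 <- read_results_matrix(path)
  expect_equal(unclass(m)[, ], unclass(m2)[, ])
  expect_equal(attr(m2, "optima"), c(0, 0, -5))
})
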