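test_that("the synthetic helix has uniform virtual bond geometry", {
  h <- synthetic_helix(30)
  d <- sqrt(rowSums(diff(h$coords)^2))
  expect_lt(max(d) - min(d), 1e-9)              # constant consecutive distance
  expect_true(all(d > 3.7 & d < 3.9))           # default parametrization
  g <- extract_geometry(h)
  expect_lt(max(g$bond_angles) - min(g$bond_angles), 1e-6)
  expect_lt(max(g$dihedrals) - min(g$dihedrals), 1e-6)
  expect_error(synthetic_helix(4), "at least 5")
})

test_that("geometry extraction is rigid-invariant and chirality-aware", {
  set.seed(10)
  h <- synthetic_helix(15)
  g <- extract_geometry(h)
  moved <- ca_trace(apply_rigid(h$coords), validate = FALSE)
  gm <- extract_geometry(moved)
  expect_equal(gm$bond_lengths, g$bond_lengths, tolerance = 1e-9)
  expect_equal(gm$bond_angles, g$bond_angles, tolerance = 1e-9)
  expect_equal(gm$dihedrals, g$dihedrals, tolerance = 1e-9)
  mirror <- ca_trace(h$coords %*% diag(c(1, 1, -1)), validate = FALSE)
  gmir <- extract_geometry(mirror)
  expect_equal(gmir$bond_lengths, g$bond_lengths, tolerance = 1e-9)
  expect_equal(gmir$bond_angles, g$bond_angles, tolerance = 1e-9)
  expect_equal(gmir$dihedrals, -g$dihedrals, tolerance = 1e-9)
  collinear <- ca_trace(cbind(c(0, 1, 2, 3, 4) * 3.8, 0, 0), validate = FALSE)
  expect_error(extract_geometry(collinear), "collinear")
  expect_error(extract_geometry(ca_trace(h$coords[1:3, ], validate = FALSE)),
               "at least 4")
})

test_that("internal-to-Cartesian construction round-trips exactly", {
  set.seed(11)
  for (k in 1:3) {
    X <- matrix(cumsum(rnorm(36, sd = 2)), 12, 3)
    tr <- ca_trace(X, validate = FALSE)
    g <- extract_geometry(tr)
    rebuilt <- internal_to_cartesian(g)
    expect_lt(superpose_rmsd(rebuilt, tr)$rmsd, 1e-9)
    g2 <- extract_geometry(rebuilt)
    expect_equal(g2$dihedrals, g$dihedrals, tolerance = 1e-9)
  }
})

test_that("distance constraints equal the distances measured on the source trace", {
  h <- synthetic_helix(12)
  g <- extract_geometry(h)
  targets <- geometry_to_distances(g)
  for (i in 5:12) {
    actual <- sqrt(colSums((h$coords[i, ] - t(h$coords[(i - 1):(i - 4), ]))^2))
    expect_equal(unname(targets[i - 4, ]), unname(actual), tolerance = 1e-9)
  }
  expect_equal(unname(targets[, "d1"]), g$bond_lengths[5:12 - 1],
               tolerance = 1e-12)
  # collinear limit at the newest angle: d(i, i-2) = b_i + b_(i-1)
  gline <- structure(list(bond_lengths = rep(3.8, 4),
                          bond_angles = c(90, 90, 180),
                          dihedrals = c(10, 10), n = 5L),
                     class = "internal_geometry")
  expect_equal(unname(geometry_to_distances(gline)[1, "d2"]), 7.6,
               tolerance = 1e-9)
})

test_that("placement energy is a sum of per-constraint deviations", {
  set.seed(12)
  prev <- matrix(rnorm(12, sd = 3), 4, 3)
  native <- rnorm(3)
  targets <- sqrt(colSums((native - t(prev))^2))
  expect_equal(placement_energy(native, prev, targets), 0)
  t2 <- targets; t2[3] <- t2[3] + 0.25
  expect_equal(placement_energy(native, prev, t2), 0.25^2)
  cand <- rnorm(3)
  hand <- 0
  for (a in 1:4)
    hand <- hand + (sqrt(sum((cand - prev[a, ])^2)) - targets[a])^2
  expect_equal(placement_energy(cand, prev, targets), hand)
  expect_equal(placement_energy(native, prev, t2, form = "absolute"), 0.25)
})

test_that("the seeded first four atoms satisfy the leading internal coordinates", {
  h <- synthetic_helix(10)
  g <- extract_geometry(h)
  set.seed(13)
  four <- seed_first_four(g)
  gf <- extract_geometry(ca_trace(four, validate = FALSE))
  expect_equal(gf$bond_lengths, g$bond_lengths[1:3], tolerance = 1e-9)
  expect_equal(gf$bond_angles, g$bond_angles[1:2], tolerance = 1e-9)
  expect_equal(gf$dihedrals, g$dihedrals[1], tolerance = 1e-9)
  set.seed(14)
  four2 <- seed_first_four(g)
  gf2 <- extract_geometry(ca_trace(four2, validate = FALSE))
  expect_equal(gf2$bond_lengths, gf$bond_lengths, tolerance = 1e-9)
})

test_that("per-atom placement solves noise-free constraints to tolerance", {
  h <- synthetic_helix(9)
  g <- extract_geometry(h)
  targets <- geometry_to_distances(g)
  prev <- h$coords[4:1, ]
  expect_true(all(abs(h$coords[5, ] - prev[1, ]) <= max(targets[1, ])))
  set.seed(15)
  fit <- place_next_ca(prev, targets[1, ])
  expect_lt(fit$energy, 1e-6)
  expect_lt(sqrt(sum((fit$position - h$coords[5, ])^2)), 1e-2)
  set.seed(15)
  fit2 <- place_next_ca(prev, targets[1, ])
  expect_identical(fit$position, fit2$position)
})

test_that("chain rebuilding reproduces the source to sub-Angstrom accuracy", {
  h <- synthetic_helix(20)
  g <- extract_geometry(h)
  rb <- rebuild_chain(g, seed = 16)
  expect_equal(nrow(rb$trace$coords), 20)
  expect_lt(superpose_rmsd(rb$trace, h)$rmsd, 0.5)
  expect_length(rb$flagged, 0)
  g2 <- extract_geometry(rb$trace)
  expect_equal(g2$bond_lengths, g$bond_lengths, tolerance = 1e-3)
  expect_equal(g2$dihedrals, g$dihedrals, tolerance = 1)
})

test_that("constraint noise is zero-mean, bounded and degrades the rebuild", {
  h <- synthetic_helix(16)
  g <- extract_geometry(h)
  expect_identical(add_constraint_noise(g, 0), g)
  set.seed(17)
  devs <- replicate(10000, add_constraint_noise(g, 0.1)$bond_lengths[1] -
                      g$bond_lengths[1])
  se <- 0.1 * g$bond_lengths[1] / sqrt(10000)
  expect_lt(abs(mean(devs)), 3 * se)
  set.seed(18)
  gn <- add_constraint_noise(g, 0.1)
  expect_true(all(gn$bond_angles > 0 & gn$bond_angles < 180))
  expect_true(all(gn$dihedrals > -180 & gn$dihedrals <= 180))
  rb_clean <- rebuild_chain(g, seed = 19)
  rb_noisy <- rebuild_chain(gn, seed = 19)
  r0 <- superpose_rmsd(rb_clean$trace, h)$rmsd
  r1 <- superpose_rmsd(rb_noisy$trace, h)$rmsd
  expect_true(is.finite(r1))
  expect_gt(r1, r0)
})

test_that("C-alpha traces survive a PDB write/read cycle", {
  h <- synthetic_helix(8)
  path <- tempfile(fileext = ".pdb")
  write_ca_pdb(h, path)
  back <- read_ca_trace(path, chain = "A")
  expect_equal(back$coords, h$coords, tolerance = 1e-3)  # 3-decimal records
  expect_equal(back$resid, 1:8)
})
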