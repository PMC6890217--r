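make_pairs <- function(P, R) {
  landmark_pairs(data.frame(
    label = sprintf("L%02d", seq_len(nrow(P))),
    px = P[, 1], py = P[, 2], pz = P[, 3],
    rx = R[, 1], ry = R[, 2], rz = R[, 3]))
}

test_that("edge discrepancy: hand values, symmetry, degenerate edge", {
  P <- rbind(c(0, 0, 0), c(2, 0, 0))
  R <- rbind(c(5, 5, 5), c(5, 5, 6))           # lengths 2 vs 1
  pairs <- make_pairs(P, R)
  expect_equal(edge_discrepancy(pairs, "L01", "L02"), 1 / 1.5,
               tolerance = 1e-12)
  # swapping the image roles leaves the value unchanged
  swapped <- make_pairs(R, P)
  expect_equal(edge_discrepancy(swapped, 1, 2),
               edge_discrepancy(pairs, 1, 2), tolerance = 1e-15)
  # identical lengths give exactly zero
  same <- make_pairs(P, rbind(c(9, 9, 9), c(9, 9, 11)))
  expect_identical(edge_discrepancy(same, 1, 2), 0)
  # coincident in both images is a digitization mistake, not zero error
  degen <- make_pairs(rbind(c(1, 1, 1), c(1, 1, 1)),
                      rbind(c(2, 2, 2), c(2, 2, 2)))
  expect_error(edge_discrepancy(degen, 1, 2), "degenerate edge")
})

test_that("triangle error: congruent zero, proportional scaling, asymmetry", {
  set.seed(11)
  tr <- rand_triple()
  P <- rbind(tr$A, tr$B, tr$C)
  pairs <- rigid_copy_pairs(P)
  expect_lt(triangle_error(pairs, "L01", "L02", "L03"), 1e-12)

  # uniform scale k: all discrepancies equal e, so t = 0 and E_t = 3 e
  k <- 1.3
  scaled <- make_pairs(P, 7 + k * P)
  e <- abs(1 - k) / (0.5 * (1 + k))
  expect_equal(triangle_error(scaled, 1, 2, 3), 3 * e, tolerance = 1e-9)

  # one perturbed edge makes E_t strictly positive
  Rm <- P; Rm[2, ] <- Rm[2, ] + c(0.5, 0, 0)
  expect_gt(triangle_error(make_pairs(P, Rm), 1, 2, 3), 0)

  # permutation invariance
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))
  vals <- vapply(perms, function(p) {
    triangle_error(scaled, p[1], p[2], p[3])
  }, numeric(1))
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-15)
})

test_that("point error matches the brute-force oracle and flags corruption", {
  set.seed(12)
  P <- spread_cloud(6)
  R <- apply_rigid(P, rand_rotation(), runif(3, -20, 20)) +
    matrix(rnorm(18, sd = 0.1), 6, 3)
  pairs <- make_pairs(P, R)
  for (i in 1:6) {
    expect_equal(point_error(pairs, i), brute_point_error(pairs, i),
                 tolerance = 1e-12)
  }

  # congruent pool: all zero
  congr <- rigid_copy_pairs(spread_cloud(5))
  for (i in 1:5) expect_lt(point_error(congr, i), 1e-12)

  # one landmark displaced 2 mm in R dominates every other's error
  P4 <- spread_cloud(4)
  R4 <- apply_rigid(P4, rand_rotation(), runif(3, -20, 20))
  R4[2, ] <- R4[2, ] + c(2, 0, 0)
  bad <- make_pairs(P4, R4)
  errs <- vapply(1:4, function(i) point_error(bad, i), numeric(1))
  expect_identical(which.max(errs), 2L)
  expect_true(all(errs[2] > errs[-2]))

  # invariant under pool reordering
  perm <- c(3, 1, 4, 2)
  expect_equal(point_error(bad[perm, ], "L02"), errs[2], tolerance = 1e-15)

  expect_error(point_error(bad[1:2, ], 1), "at least 3")
})

test_that("rank_landmarks eliminates the corrupted pair first", {
  set.seed(13)
  for (k in 1:10) {
    P <- spread_cloud(6)
    R <- apply_rigid(P, rand_rotation(), runif(3, -20, 20))
    victim <- sample(6, 1)
    dir <- rnorm(3); dir <- dir / norm3(dir)
    R[victim, ] <- R[victim, ] + 2 * dir       # 2 mm corruption, no noise
    rk <- rank_landmarks(make_pairs(P, R))
    expect_identical(rk$elimination_order[1], sprintf("L%02d", victim))
    expect_false(sprintf("L%02d", victim) %in% rk$basic_triple)
  }
})

test_that("rank_landmarks structure, 3-pair case, and tie handling", {
  set.seed(14)
  pairs <- rigid_copy_pairs(spread_cloud(3))
  rk <- rank_landmarks(pairs)
  expect_identical(rk$basic_triple, pairs$label)
  expect_identical(rk$elimination_order, character(0))
  expect_true(is.na(rk$fourth_pair))

  expect_error(rank_landmarks(rigid_copy_pairs(spread_cloud(3))[1:2, ]),
               "at least 3")

  # 5 exactly congruent pairs: every label appears once, deterministic,
  # and the selected triple still registers with zero system error
  pairs5 <- rigid_copy_pairs(spread_cloud(5))
  rk5 <- rank_landmarks(pairs5)
  expect_setequal(c(rk5$basic_triple, rk5$elimination_order), pairs5$label)
  expect_identical(rk5$fourth_pair,
                   rk5$elimination_order[length(rk5$elimination_order)])
  rk5b <- rank_landmarks(pairs5)
  expect_identical(rk5, rk5b)
  expect_lt(system_error(pairs5, rk5)$system_error_mm, 1e-9)

  # collinear surviving triple is refused
  Pcol <- rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0))
  expect_error(rank_landmarks(rigid_copy_pairs(Pcol)), "degenerate")
})

test_that("system error: congruent zero, known displacement, residuals", {
  set.seed(15)
  P <- spread_cloud(6)
  pairs <- rigid_copy_pairs(P)
  rk <- rank_landmarks(pairs)
  se <- system_error(pairs, rk)
  expect_lt(se$system_error_mm, 1e-9)
  expect_length(se$residuals, 3)
  expect_true(all(se$residuals < 1e-9))

  # with 4 pairs, displacing one by a known vector leaves the exact triple
  # as basic and the corrupted pair held out: error equals |d| exactly
  d <- c(0.3, -0.4, 0.5)
  pairs4 <- rigid_copy_pairs(spread_cloud(4))
  pairs4[2, c("rx", "ry", "rz")] <- pairs4[2, c("rx", "ry", "rz")] + d
  rk4 <- rank_landmarks(pairs4)
  expect_identical(rk4$fourth_pair, "L02")
  expect_setequal(rk4$basic_triple, c("L01", "L03", "L04"))
  expect_equal(system_error(pairs4, rk4)$system_error_mm, norm3(d),
               tolerance = 1e-9)
  # mean-residual flag aggregates over all held-out pairs (6-pair, noisy)
  pairs2 <- pairs
  pairs2$rx <- pairs2$rx + rnorm(6, sd = 0.05)
  rk2 <- rank_landmarks(pairs2)
  sem <- system_error(pairs2, rk2, use_mean = TRUE)
  expect_equal(sem$system_error_mm, mean(sem$residuals), tolerance = 1e-15)

  expect_error(system_error(pairs[1:3, ], rank_landmarks(pairs[1:3, ])),
               "at least 4")
})

test_that("errors and system error are invariant under rigid motions", {
  set.seed(16)
  P <- spread_cloud(5)
  R <- apply_rigid(P, rand_rotation(), runif(3, -20, 20)) +
    matrix(rnorm(15, sd = 0.05), 5, 3)
  pairs <- make_pairs(P, R)
  ref_E <- vapply(1:5, function(i) point_error(pairs, i), numeric(1))
  ref_se <- system_error(pairs)$system_error_mm

  for (k in 1:5) {
    Q1 <- rand_rotation(); t1 <- runif(3, -50, 50)   # applied to P image
    Q2 <- rand_rotation(); t2 <- runif(3, -50, 50)   # applied to R image
    moved <- make_pairs(apply_rigid(P, Q1, t1), apply_rigid(R, Q2, t2))
    expect_equal(vapply(1:5, function(i) point_error(moved, i), numeric(1)),
                 ref_E, tolerance = 1e-9)
    expect_equal(system_error(moved)$system_error_mm, ref_se,
                 tolerance = 1e-8)
  }
})

test_that("mean system error increases with digitization noise", {
  set.seed(17)
  mean_se <- vapply(c(0.05, 0.1, 0.2), function(sg) {
    errs <- vapply(1:200, function(k) {
      P <- spread_cloud(6)
      R <- apply_rigid(P, rand_rotation(), runif(3, -20, 20))
      noisy <- make_pairs(P + matrix(rnorm(18, sd = sg), 6, 3),
                          R + matrix(rnorm(18, sd = sg), 6, 3))
      system_error(noisy)$system_error_mm
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_true(all(diff(mean_se) > 0))
})
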