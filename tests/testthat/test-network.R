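test_that("reweight scales the within-omics blocks and nothing else", {
  net <- toy_network(seed = 11)

  expect_equal(reweight(net, 1, 1), net)

  rw <- reweight(net, 0.05, 20)
  expect_equal(rw$gg, net$gg * 0.05)
  expect_equal(rw$mm, net$mm * 20)
  expect_equal(rw$gm, net$gm)
  expect_true(isSymmetric(unname(rw$gg)))
  expect_true(min(rw$gg, rw$mm, rw$gm) >= 0)

  # forced arithmetic on single weights
  fs <- feature_set(c("a", "b"), c("x", "y"))
  n2 <- multi_omics_network(fs, gg = matrix(c(0, 900, 900, 0), 2),
                            mm = matrix(c(0, 10, 10, 0), 2),
                            gm = matrix(1, 2, 2))
  r2 <- reweight(n2, 0.05, 20)
  expect_equal(r2$gg[1, 2], 45)
  expect_equal(r2$mm[1, 2], 200)
  expect_equal(r2$gm, n2$gm)

  expect_error(reweight(net, 0, 1), "positive")
  expect_error(reweight(net, 1, -2), "positive")
})

test_that("reweight is multiplicative in its parameters (per-block linearity)", {
  net <- toy_network(seed = 12)
  for (ab in list(c(2, 3), c(0.5, 0.1), c(7, 0.25))) {
    a <- ab[1]; b <- ab[2]
    expect_equal(reweight(net, a * b, 1)$gg,
                 reweight(reweight(net, b, 1), a, 1)$gg)
    expect_equal(reweight(net, 1, a * b)$mm,
                 reweight(reweight(net, 1, b), 1, a)$mm)
  }
})

test_that("symmetrize averages a matrix with its transpose and is idempotent", {
  expect_equal(symmetrize(matrix(c(0, 0, 2, 0), 2)),
               matrix(c(0, 1, 1, 0), 2))
  set.seed(21)
  M <- matrix(runif(49), 7)
  S <- symmetrize(M)
  expect_equal(S - t(S), matrix(0, 7, 7))
  expect_equal(symmetrize(S), S)
  sym <- matrix(c(1, 2, 2, 5), 2)
  expect_equal(symmetrize(sym), sym)
  expect_error(symmetrize(matrix(1, 2, 3)), "square")
})

test_that("denoise keeps exactly the top fraction of nonzero edges per block", {
  net <- toy_network(seed = 13)
  expect_equal(denoise(net, 1, 1, 1), net)

  # 5 distinct gg weights {9,7,5,3,1}: keep 0.4 retains exactly 9 and 7
  fs <- feature_set(sprintf("g%d", 1:5), "m1")
  gg <- matrix(0, 5, 5)
  gg[1, 2] <- 9; gg[1, 3] <- 7; gg[2, 4] <- 5; gg[3, 5] <- 3; gg[4, 5] <- 1
  gg <- gg + t(gg)
  gm <- matrix(1, 5, 1)
  nd <- denoise(multi_omics_network(fs, gg = gg, gm = gm),
                keep_gg = 0.4, keep_mm = 1, keep_gm = 1)
  expect_equal(sort(nd$gg[upper.tri(nd$gg) & nd$gg != 0]), c(7, 9))
  expect_true(isSymmetric(unname(nd$gg)))

  # independent brute-force oracle on a random block
  keep <- 0.3
  ug <- unname(net$gg); ug[!upper.tri(ug)] <- 0
  expected_idx <- brute_force_keep(ug, keep)
  nd2 <- denoise(net, keep_gg = keep, keep_mm = 1, keep_gm = 1)
  ug2 <- unname(nd2$gg); ug2[!upper.tri(ug2)] <- 0
  expect_equal(which(ug2 != 0), expected_idx)

  # all-equal weights: tie-break keeps exactly ceil(keep * E) edges,
  # chosen in (row, column) order: (1,2) (1,3) (1,4) (1,5) (2,3)
  ggt <- matrix(0, 5, 5); ggt[upper.tri(ggt)] <- 4; ggt <- ggt + t(ggt)
  ndt <- denoise(multi_omics_network(fs, gg = ggt, gm = gm),
                 keep_gg = 0.5, keep_mm = 1, keep_gm = 1)
  kept <- which(upper.tri(ndt$gg) & ndt$gg != 0, arr.ind = TRUE)
  kept <- kept[order(kept[, 1], kept[, 2]), , drop = FALSE]
  expect_equal(nrow(kept), ceiling(0.5 * 10))
  expect_equal(unname(kept),
               cbind(c(1L, 1L, 1L, 1L, 2L), c(2L, 3L, 4L, 5L, 3L)))
})

test_that("denoise never increases weights or edge counts and warns on empty blocks", {
  net <- toy_network(seed = 14)
  nd <- denoise(net, 0.2, 0.5, 0.3)
  expect_true(all(nd$gg <= net$gg))
  expect_true(all(nd$mm <= net$mm))
  expect_true(all(nd$gm <= net$gm))
  expect_lte(sum(nd$gg != 0), sum(net$gg != 0))

  fs <- feature_set(c("a", "b"), c("x", "y"))
  empty_mm <- multi_omics_network(fs, gg = matrix(c(0, 5, 5, 0), 2),
                                  gm = matrix(2, 2, 2))
  expect_message(out <- denoise(empty_mm, 0.5, 0.5, 0.5), "no nonzero")
  expect_equal(out$mm, empty_mm$mm)

  expect_error(denoise(net, 0, 1, 1), "\\(0, 1\\]")
  expect_error(denoise(net, 1, 1.5, 1), "\\(0, 1\\]")
})

test_that("column_normalize yields a column-stochastic matrix and is idempotent", {
  set.seed(31)
  M <- matrix(rexp(60), 6, 10)
  N <- column_normalize(M)
  expect_equal(unname(colSums(N)), rep(1, 10), tolerance = 1e-12)
  expect_equal(column_normalize(N), N)

  Z <- matrix(c(1, 1, 0, 0), 2)
  NZ <- column_normalize(Z)
  expect_equal(NZ[, 1], c(0.5, 0.5))
  expect_equal(NZ[, 2], c(0, 0))  # zero columns stay zero (sub-stochastic)

  expect_error(column_normalize(matrix(c(1, -1), 1)), "nonnegative")
})

test_that("compose/decompose are exact inverses with genes-first ordering", {
  net <- toy_network(seed = 15)
  full <- compose(net)
  expect_equal(decompose(full, net$features), net)
  expect_equal(compose(decompose(full, net$features)), full)

  fs <- feature_set(c("g1", "g2"), "m1")
  n3 <- multi_omics_network(fs, gg = matrix(c(0, 2, 2, 0), 2),
                            gm = matrix(c(5, 0), 2, 1))
  M <- compose(n3)
  expect_equal(dim(M), c(3L, 3L))
  expect_equal(rownames(M), c("g1", "g2", "m1"))
  expect_equal(M[1, 3], 5)
  expect_equal(M[3, 1], 5)

  expect_error(decompose(matrix(0, 4, 4), fs), "feature")
})

test_that("network validation enforces symmetry, ranges and zero diagonals", {
  fs <- feature_set(c("a", "b"), c("x", "y"))
  expect_error(multi_omics_network(fs, gg = matrix(c(0, 1, 2, 0), 2)),
               "symmetric")
  expect_error(multi_omics_network(fs, gm = matrix(-1, 2, 2)),
               "nonnegative")
  expect_error(multi_omics_network(fs, gm = matrix(1000, 2, 2)),
               "999")
  withdiag <- multi_omics_network(fs, gg = matrix(c(3, 1, 1, 3), 2))
  expect_equal(unname(diag(withdiag$gg)), c(0, 0))
})
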