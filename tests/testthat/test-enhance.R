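# Independent straight-line reference of the seven-step enhancement,
# written directly against the full matrices.
reference_enhance <- function(net, sim, cfg) {
  ng <- length(net$features$genes)
  n <- length(net$features)
  gi <- seq_len(ng); mi <- (ng + 1):n
  scale_blocks <- function(M, lg, lm) {
    M[gi, gi] <- M[gi, gi] * lg
    M[mi, mi] <- M[mi, mi] * lm
    M
  }
  s0t <- scale_blocks(compose(net), cfg$lambda_g, cfg$lambda_m)
  E <- compose(sim)
  if (cfg$reweight_similarity)
    E <- scale_blocks(E, cfg$lambda_g, cfg$lambda_m)
  cs <- colSums(E)
  E[, cs > 0] <- sweep(E[, cs > 0, drop = FALSE], 2, cs[cs > 0], "/")
  S <- (1 - cfg$alpha) * solve(diag(n) - cfg$alpha * E, s0t)
  S <- (S + t(S)) / 2
  diag(S) <- 0
  cut_block <- function(M, rows, cols, keep, symmetric) {
    W <- matrix(0, n, n)
    W[rows, cols] <- M[rows, cols]
    if (symmetric) W[!upper.tri(W)] <- 0
    kept <- brute_force_keep(W, keep)
    out <- matrix(0, n, n)
    out[kept] <- M[kept]
    if (symmetric) out <- out + t(out)
    out
  }
  D <- cut_block(S, gi, gi, cfg$keep_gg, TRUE) +
    cut_block(S, mi, mi, cfg$keep_mm, TRUE) +
    cut_block(S, gi, mi, cfg$keep_gm, FALSE) +
    t(cut_block(S, gi, mi, cfg$keep_gm, FALSE))
  cs2 <- colSums(D)
  D[, cs2 > 0] <- sweep(D[, cs2 > 0, drop = FALSE], 2, cs2[cs2 > 0], "/")
  D
}

test_that("rwr_matrix degenerates correctly at alpha = 0 and identity walk", {
  set.seed(51)
  S0 <- matrix(runif(36), 6)
  E <- column_normalize(matrix(runif(36), 6))
  out0 <- rwr_matrix(E, S0, alpha = 0)
  expect_equal(unname(as.matrix(out0)), S0, ignore_attr = TRUE)

  outI <- rwr_matrix(diag(6), S0, alpha = 0.75)
  expect_equal(unname(outI), S0, tolerance = 1e-5, ignore_attr = TRUE)
})

test_that("iterative walk matches the direct linear solve", {
  set.seed(52)
  for (n in c(10, 20, 40)) {
    E <- column_normalize(matrix(rexp(n * n) *
                                   (runif(n * n) < 0.3), n))
    S0 <- matrix(runif(n * n), n)
    it <- rwr_matrix(E, S0, 0.75, tol = 1e-8)
    dir <- rwr_matrix(E, S0, 0.75, solver = "direct")
    expect_lt(max(abs(it - dir)), 1e-5)
    expect_true(attr(it, "residual") < 1e-8)
    expect_true(attr(it, "iterations") >= 1)
  }
})

test_that("walk errors on non-convergence and bad inputs", {
  set.seed(53)
  E <- column_normalize(matrix(runif(25), 5))
  S0 <- matrix(runif(25), 5)
  expect_error(rwr_matrix(E, S0, 0.99, tol = 1e-14, max_iter = 3),
               "did not converge")
  expect_error(rwr_matrix(E, S0, 1), "alpha")
  expect_error(rwr_matrix(E * 3, S0, 0.5), "column sums")
  expect_error(rwr_matrix(E, S0[1:3, ], 0.5), "dimensions")
})

test_that("sparse and dense representations give identical walks", {
  set.seed(54)
  n <- 50
  E <- matrix(0, n, n)
  idx <- sample(n * n, 120)
  E[idx] <- runif(120)
  E <- column_normalize(E)
  S0 <- matrix(runif(n * n), n)
  dense <- rwr_matrix(E, S0, 0.75, sparse_threshold = 0)    # force dense
  sparse <- rwr_matrix(E, S0, 0.75, sparse_threshold = 1)   # force sparse
  expect_lt(max(abs(dense - sparse)), 1e-10)
})

test_that("enhance reduces to column-normalized reweighting when degenerate", {
  net <- toy_network(seed = 55)
  sim <- toy_similarity(net$features, seed = 56)
  cfg <- weight_config(alpha = 0, keep_gg = 1, keep_mm = 1, keep_gm = 1)
  se <- enhance(net, sim, cfg)
  expected <- column_normalize(compose(reweight(net, cfg$lambda_g,
                                                cfg$lambda_m)))
  expect_equal(compose(se), expected, tolerance = 1e-12)
})

test_that("enhance matches an independent straight-line reference", {
  net <- toy_network(ng = 10, nm = 4, seed = 57)
  sim <- toy_similarity(net$features, seed = 58)
  for (cfg in list(weight_config(),
                   weight_config(lambda_g = 1, lambda_m = 1),
                   weight_config(reweight_similarity = FALSE),
                   weight_config(keep_gg = 0.5, keep_mm = 0.8,
                                 keep_gm = 0.6))) {
    got <- compose(enhance(net, sim, cfg, solver = "direct"))
    want <- reference_enhance(net, sim, cfg)
    expect_equal(unname(got), unname(want), tolerance = 1e-8)
  }
})

test_that("enhanced network is column-stochastic up to zero columns", {
  net <- toy_network(ng = 12, nm = 5, seed = 59)
  sim <- toy_similarity(net$features, seed = 60)
  se <- compose(enhance(net, sim, weight_config()))
  cs <- colSums(se)
  expect_true(all(abs(cs[cs > 0] - 1) < 1e-12))
  expect_true(all(se >= 0))
})

test_that("enhancement is equivariant under feature permutation", {
  net <- toy_network(ng = 6, nm = 3, seed = 61)
  sim <- toy_similarity(net$features, seed = 62)
  cfg <- weight_config(keep_gg = 1, keep_mm = 1, keep_gm = 1)
  se1 <- compose(enhance(net, sim, cfg, solver = "direct"))

  pg <- c(3, 1, 6, 2, 5, 4); pm <- c(2, 3, 1)
  fs2 <- feature_set(net$features$genes[pg], net$features$metabolites[pm])
  perm_net <- multi_omics_network(fs2, gg = net$gg[pg, pg],
                                  mm = net$mm[pm, pm],
                                  gm = net$gm[pg, pm])
  perm_sim <- decompose(compose(sim)[c(pg, 6 + pm), c(pg, 6 + pm)], fs2,
                        weight_scale = "similarity")
  se2 <- compose(enhance(perm_net, perm_sim, cfg, solver = "direct"))
  ids <- feature_ids(net$features)
  expect_equal(se2[ids, ids], se1[ids, ids], tolerance = 1e-10)
})
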