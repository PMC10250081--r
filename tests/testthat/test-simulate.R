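test_that("simulation config validates its parameters", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(n_signal_genes = 10, n_genes = 5),
               "exceed")
  expect_error(simulation_config(sigma_gene = 0), "positive")
  expect_error(simulation_config(rho_gg = c(signal = 1, noise = 0.2,
                                            cross = 0.2)), "\\[0, 1\\)")
  expect_error(simulation_config(rho_gm = c(0.2, 0.1)), "4 entries")
})

test_that("omics simulation is reproducible and group means are correct", {
  cfg <- simulation_config(n_genes = 40, n_signal_genes = 5,
                           n_metabolites = 8, n_signal_metabolites = 2,
                           n_cases = 25, n_controls = 25, seed = 91)
  a <- simulate_omics(cfg)
  b <- simulate_omics(cfg)
  expect_identical(a$data$values, b$data$values)
  expect_identical(a$truth, b$truth)
  expect_length(a$truth$signal_genes, 5)
  expect_length(a$truth$signal_metabolites, 2)

  # law-of-large-numbers check on means at inflated sample size
  cfg_big <- simulation_config(n_genes = 6, n_signal_genes = 2,
                               n_metabolites = 4,
                               n_signal_metabolites = 1,
                               n_cases = 10000, n_controls = 10000,
                               seed = 92)
  big <- simulate_omics(cfg_big)
  cases <- big$data$values[big$data$group == "case", , drop = FALSE]
  ctrls <- big$data$values[big$data$group == "control", , drop = FALSE]
  sg <- big$truth$signal_genes[1]
  # 3 sigma / sqrt(n) tolerance
  expect_equal(mean(cases[, sg]), 6.15, tolerance = 3 * 2 / sqrt(10000))
  expect_equal(mean(ctrls[, sg]), 6, tolerance = 3 * 2 / sqrt(10000))
  noise_g <- setdiff(big$data$features$genes, big$truth$signal_genes)[1]
  expect_equal(mean(cases[, noise_g]), 6, tolerance = 3 * 2 / sqrt(10000))
})

test_that("sampled correlations match the block-constant targets", {
  cfg <- simulation_config(n_genes = 8, n_signal_genes = 3,
                           n_metabolites = 6, n_signal_metabolites = 3,
                           n_cases = 50, n_controls = 10000, seed = 93)
  out <- simulate_omics(cfg)
  X <- out$data$values[out$data$group == "control", , drop = FALSE]
  sm <- out$truth$signal_metabolites
  sg <- out$truth$signal_genes
  # absolute +-0.03 covers 3 standard errors of r at n = 10000
  expect_lt(abs(cor(X[, sm[1]], X[, sm[2]]) - 0.30), 0.03)
  expect_lt(abs(cor(X[, sg[1]], X[, sg[2]]) - 0.25), 0.03)
  expect_lt(abs(cor(X[, sg[1]], X[, sm[1]]) - 0.20), 0.03)
  expect_lt(abs(sd(X[, sg[1]]) - 2), 0.06)
  expect_lt(abs(sd(X[, sm[1]]) - 2.5), 0.08)
})

test_that("null configuration yields uniform t-test p-values", {
  cfg <- simulation_config(
    n_genes = 499, n_signal_genes = 5, n_metabolites = 2,
    n_signal_metabolites = 1, n_cases = 40, n_controls = 40,
    mu_signal_gene = 6, mu_signal_met = 0,
    rho_gg = c(signal = 0, noise = 0, cross = 0),
    rho_mm = c(signal = 0, noise = 0, cross = 0),
    rho_gm = c(signal_signal = 0, signal_noise = 0, noise_signal = 0,
               noise_noise = 0),
    seed = 94)
  out <- simulate_omics(cfg)
  p <- test_scores(out$data)
  ks <- stats::ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("infeasible correlation structures are rejected by the repair", {
  # strongly negative-definite block structure: within-block correlation
  # near zero but cross-block near one cannot be a correlation matrix at
  # these block sizes
  cfg <- simulation_config(
    n_genes = 50, n_signal_genes = 25, n_metabolites = 10,
    n_signal_metabolites = 5,
    rho_gg = c(signal = 0.01, noise = 0.01, cross = 0.9),
    seed = 95)
  expect_error(simulate_omics(cfg), "infeasible")
})

test_that("network generator hits densities and enrichment contract", {
  net <- simulate_network(120, 12, truth = NULL, density_gg = 0.2,
                          density_mm = 0.3, density_gm = 0.1,
                          enrichment = 1, seed = 96)
  ut <- upper.tri(net$gg)
  # binomial 3-sigma bands on the realized densities
  expect_lt(abs(mean(net$gg[ut] != 0) - 0.2), 0.015)
  expect_lt(abs(mean(net$gm != 0) - 0.1), 0.025)
  expect_true(all(compose(net) <= 999))
  nz <- net$gg[ut][net$gg[ut] != 0]
  expect_true(all(nz >= 1 & nz == round(nz)))

  # enrichment raises signal-feature gm connectivity (stochastic
  # dominance checked over seeds)
  truth <- list(signal_genes = sprintf("g%03d", 1:15),
                signal_metabolites = sprintf("m%02d", 1:6))
  diff_irs <- vapply(1:12, function(s) {
    n2 <- simulate_network(120, 12, truth, density_gm = 0.08,
                           enrichment = 3, seed = 200 + s)
    v <- irs(n2, "gm", side = "gene")
    mean(v[truth$signal_genes]) -
      mean(v[setdiff(n2$features$genes, truth$signal_genes)])
  }, numeric(1))
  expect_gt(mean(diff_irs), 0)
})

test_that("subsampling induces the exact sub-network", {
  net <- toy_network(ng = 5, nm = 3, seed = 97)
  expect_equal(subsample_network(net, net$features$genes,
                                 net$features$metabolites), net)
  keep <- net$features$genes[c(2, 4)]
  sub <- subsample_network(net, keep, net$features$metabolites)
  expect_equal(sub$gg, net$gg[c(2, 4), c(2, 4)])
  expect_equal(sub$gm, net$gm[c(2, 4), ])
  expect_lte(sum(compose(sub) != 0), sum(compose(net) != 0))
  expect_error(subsample_network(net, "nope", net$features$metabolites),
               "unknown identifiers")
})

test_that("study tables are reproducible with correct bookkeeping", {
  cfg <- simulation_config(n_genes = 40, n_signal_genes = 5,
                           n_metabolites = 8, n_signal_metabolites = 2,
                           n_cases = 15, n_controls = 15, seed = 98)
  grid <- list(c(0.05, 20), c(0.5, 5))
  st1 <- run_study(cfg, weight_grid = grid, n_reps = 2, ks = c(5, 10))
  st2 <- run_study(cfg, weight_grid = grid, n_reps = 2, ks = c(5, 10))
  expect_identical(st1, st2)
  # rows: reps x (general + enhanced + |grid|) x |ks|
  expect_equal(nrow(st1), 2 * (2 + length(grid)) * 2)
  expect_equal(sum(st1$method == "reweighted"), 2 * length(grid) * 2)
  expect_true(all(st1$combined <= st1$k))

  # grid point (1, 1) duplicates the unrebalanced baseline
  st3 <- run_study(cfg, weight_grid = list(c(1, 1)), n_reps = 1,
                   ks = c(10))
  enh <- st3[st3$method == "enhanced", c("true_signal_genes",
                                         "true_signal_metabolites",
                                         "combined")]
  rew <- st3[st3$method == "reweighted", c("true_signal_genes",
                                           "true_signal_metabolites",
                                           "combined")]
  expect_equal(unname(unlist(enh)), unname(unlist(rew)))

  sm <- summarize_study(st1)
  expect_equal(nrow(sm), (2 + length(grid)) * 2)
  expect_true(all(c("mean_combined", "se_combined") %in% colnames(sm)))
})
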