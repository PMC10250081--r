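# Fixtures are built in code, independently of the generators under test.

# Random undirected block network with all nodes connected (sorted ids, so
# edge-list round trips are exact).
toy_network <- function(ng = 8, nm = 4, seed = 1, scale = 999,
                        density = 0.6) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(ng))
  mets <- sprintf("m%02d", seq_len(nm))
  rand_sym <- function(n) {
    M <- matrix(0, n, n)
    ut <- upper.tri(M)
    w <- ifelse(runif(sum(ut)) < density, ceiling(runif(sum(ut)) * scale), 0)
    M[ut] <- w
    M + t(M)
  }
  gg <- rand_sym(ng)
  mm <- rand_sym(nm)
  gm <- matrix(ifelse(runif(ng * nm) < density,
                      ceiling(runif(ng * nm) * scale), 0), ng, nm)
  # guarantee no isolated nodes
  for (i in seq_len(ng)) if (all(gm[i, ] == 0) && all(gg[i, ] == 0))
    gm[i, 1 + (i %% nm)] <- ceiling(runif(1) * scale)
  for (j in seq_len(nm)) if (all(gm[, j] == 0) && all(mm[j, ] == 0))
    gm[1 + (j %% ng), j] <- ceiling(runif(1) * scale)
  multi_omics_network(feature_set(genes, mets), gg = gg, mm = mm, gm = gm)
}

# Similarity-scale network from random profiles (independent of
# build_similarity).
toy_similarity <- function(fs, seed = 2, n_samples = 25) {
  set.seed(seed)
  ids <- feature_ids(fs)
  X <- matrix(rnorm(n_samples * length(ids)), n_samples)
  C <- abs(stats::cor(X))
  diag(C) <- 0
  dimnames(C) <- list(ids, ids)
  decompose(C, fs, weight_scale = "similarity")
}

# Small omics dataset with a two-group design and a known mean shift on
# the first `n_shift` features.
toy_dataset <- function(fs, n_per_group = 15, n_shift = 0, shift = 2,
                        seed = 3) {
  set.seed(seed)
  ids <- feature_ids(fs)
  n <- 2 * n_per_group
  X <- matrix(rnorm(n * length(ids)), n, length(ids))
  if (n_shift > 0)
    X[seq_len(n_per_group), seq_len(n_shift)] <-
      X[seq_len(n_per_group), seq_len(n_shift)] + shift
  colnames(X) <- ids
  omics_dataset(X, fs, design = "two_group",
                group = rep(c("case", "control"), each = n_per_group))
}

# Independent brute-force top-fraction edge cut used as the denoising
# oracle: rank all nonzero entries of a weight matrix and keep
# ceil(keep * E), breaking ties by the documented (weight desc, row,
# column) order. Returns sorted linear indices of retained entries.
brute_force_keep <- function(W, keep) {
  nz <- which(W != 0)
  nr <- nrow(W)
  row <- (nz - 1L) %% nr + 1L
  col <- (nz - 1L) %/% nr + 1L
  ord <- order(-W[nz], row, col)
  sort(nz[ord][seq_len(ceiling(keep * length(nz)))])
}
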