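#' Convert two-sided p-values into nonnegative association scores
#'
#' Maps each p-value to `qnorm(1 - p/2)`, the absolute z-score that would
#' have produced it in a two-sided test. `p = 1` maps to 0 and smaller
#' p-values map monotonically to larger scores. Zeros are clamped to a floor
#' of `1e-300` (score about 37) with a warning, since an exactly-zero
#' p-value would otherwise give an infinite score that dominates the
#' diffusion.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Nonnegative scores, same length and names as `p`.
#' @examples
#' scores_from_pvalues(c(1, 0.05))
#' @export
scores_from_pvalues <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]")
  if (any(p == 0)) {
    warning("p-values of 0 clamped to 1e-300; affected features will ",
            "dominate the initial scores")
    p[p == 0] <- 1e-300
  }
  stats::qnorm(1 - p / 2)
}

#' Per-feature differential tests on a case/control omics dataset
#'
#' One two-sided p-value per feature: a Welch two-sample t-test for the
#' `two_group` design (Student's equal-variance test available via
#' `var_equal = TRUE`), or a paired t-test for the `paired` design.
#' Features whose statistic is undefined (zero variance everywhere) get
#' `p = 1` with a warning.
#'
#' @param data an [omics_dataset()] with a `two_group` or `paired` design
#'   and at least 2 samples per group.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return Named vector of p-values over `feature_ids(data$features)`.
#' @export
test_scores <- function(data, var_equal = FALSE) {
  stopifnot(inherits(data, "omics_dataset"))
  if (!data$design %in% c("two_group", "paired"))
    stop("test_scores requires a 'two_group' or 'paired' design")
  g <- data$group
  lv <- levels(g)
  X1 <- data$values[g == lv[1L], , drop = FALSE]
  X2 <- data$values[g == lv[2L], , drop = FALSE]
  if (nrow(X1) < 2L || nrow(X2) < 2L)
    stop("each group needs at least 2 samples")
  if (data$design == "paired") {
    X1 <- X1[order(data$pair[g == lv[1L]]), , drop = FALSE]
    X2 <- X2[order(data$pair[g == lv[2L]]), , drop = FALSE]
    D <- X1 - X2
    n <- nrow(D)
    m <- colMeans(D)
    s <- apply(D, 2L, stats::sd)
    tt <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(tt), df = n - 1L)
  } else {
    n1 <- nrow(X1); n2 <- nrow(X2)
    m1 <- colMeans(X1); m2 <- colMeans(X2)
    v1 <- apply(X1, 2L, stats::var); v2 <- apply(X2, 2L, stats::var)
    if (var_equal) {
      sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
      tt <- (m1 - m2) / sqrt(sp * (1 / n1 + 1 / n2))
      df <- n1 + n2 - 2
    } else {
      se2 <- v1 / n1 + v2 / n2
      tt <- (m1 - m2) / sqrt(se2)
      df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    }
    p <- 2 * stats::pt(-abs(tt), df = df)
  }
  bad <- !is.finite(p)
  if (any(bad)) {
    warning(sprintf("%d feature(s) with undefined statistic set to p = 1",
                    sum(bad)))
    p[bad] <- 1
  }
  stats::setNames(p, colnames(data$values))
}

#' Diffuse association scores on an enhanced network
#'
#' Iterates `v_{t+1} = beta * SE %*% v_t + (1 - beta) * v0` from `v_0 = v0`
#' until the L1 norm of successive differences drops below `tol`; the fixed
#' point is `(1 - beta) * solve(I - beta SE) %*% v0`. Scores of
#' well-connected features are reinforced by their neighbourhoods while the
#' restart term anchors every feature to its own evidence.
#'
#' @param SE column-(sub)stochastic matrix (composed enhanced network).
#' @param v0 nonnegative initial score vector.
#' @param beta restart mixing in `[0, 1)`.
#' @param tol,max_iter convergence control, as in [rwr_matrix()].
#' @param solver `"iterative"` or `"direct"`.
#' @return Converged score vector with attributes `iterations`, `residual`.
#' @export
diffuse <- function(SE, v0, beta, tol = 1e-6, max_iter = 1000L,
                    solver = c("iterative", "direct")) {
  if (length(v0) != nrow(SE)) stop("length of v0 must match SE")
  if (any(v0 < 0)) stop("initial scores must be nonnegative")
  out <- rwr_matrix(SE, v0, beta, tol = tol, max_iter = max_iter,
                    solver = match.arg(solver))
  if (!is.null(names(v0))) names(out) <- names(v0)
  out
}

#' Prioritize disease-associated genes and metabolites
#'
#' End-to-end run over a harmonized general network, similarity matrix and
#' disease evidence: enhance the network ([enhance()]), turn p-values into
#' initial scores ([scores_from_pvalues()]), diffuse them ([diffuse()]) and
#' rank all features on one combined list, descending by diffused score.
#' Ties are broken deterministically: genes before metabolites, then
#' identifier order.
#'
#' @param net general [multi_omics_network()].
#' @param sim similarity [multi_omics_network()] on the same features
#'   (built with [build_similarity()]); not used by the `"general"`
#'   variant.
#' @param evidence either an [omics_dataset()] with a testable design (then
#'   [test_scores()] is run) or a named numeric vector of p-values covering
#'   the network's features. Features of the network missing from a p-value
#'   vector get `p = 1`.
#' @param cfg a [weight_config()].
#' @param variant which pipeline to run:
#'   * `"reweighted"` — full method: rebalance both matrices, enhance,
#'     diffuse (the default);
#'   * `"reweighted_s0"` — rebalance the general network only;
#'   * `"enhanced"` — enhancement without rebalancing
#'     (`lambda_g = lambda_m = 1`);
#'   * `"general"` — no enhancement: diffuse on the column-normalized
#'     denoised general network.
#' @param solver passed to the fixed-point solvers.
#' @return An object of class `association_scores`: a data frame with
#'   columns `feature`, `type`, `pvalue`, `v0`, `v`, `rank`,
#'   `rank_in_type`, sorted by rank.
#' @export
prioritize <- function(net, sim = NULL, evidence, cfg = weight_config(),
                       variant = c("reweighted", "reweighted_s0",
                                   "enhanced", "general"),
                       solver = c("iterative", "direct")) {
  stopifnot(inherits(net, "multi_omics_network"),
            inherits(cfg, "weight_config"))
  variant <- match.arg(variant)
  solver <- match.arg(solver)

  if (inherits(evidence, "omics_dataset")) {
    if (!same_features(net$features, evidence$features))
      stop("network and dataset feature sets differ; run harmonize() first")
    p <- test_scores(evidence)
  } else {
    if (is.null(names(evidence)))
      stop("a p-value vector must be named by feature identifier")
    ids <- feature_ids(net$features)
    p <- rep(1, length(ids))
    names(p) <- ids
    known <- intersect(names(evidence), ids)
    if (length(known) == 0L) stop("no p-value names match the network")
    p[known] <- evidence[known]
  }
  p <- p[feature_ids(net$features)]

  cfg_run <- cfg
  if (variant == "enhanced") {
    cfg_run$lambda_g <- 1; cfg_run$lambda_m <- 1
  }
  if (variant == "reweighted_s0") cfg_run$reweight_similarity <- FALSE

  if (variant == "general") {
    s0d <- denoise(net, cfg$keep_gg, cfg$keep_mm, cfg$keep_gm)
    SE <- column_normalize(compose(s0d))
  } else {
    if (is.null(sim))
      stop("variant '", variant, "' needs a similarity matrix")
    se_net <- enhance(net, sim, cfg_run, solver = solver)
    SE <- compose(se_net)
  }

  v0 <- scores_from_pvalues(p)
  v <- diffuse(SE, v0, cfg$beta, tol = cfg$tol, max_iter = cfg$max_iter,
               solver = solver)
  rank_scores(net$features, p, v0, as.numeric(v),
              iterations = attr(v, "iterations"),
              residual = attr(v, "residual"), variant = variant)
}

# Deterministic combined ranking: score desc, genes before metabolites,
# identifier lexicographic.
rank_scores <- function(features, p, v0, v, iterations = NULL,
                        residual = NULL, variant = NULL) {
  ids <- feature_ids(features)
  type <- feature_types(features)
  ord <- order(-v, match(type, c("gene", "metabolite")), ids)
  rk <- integer(length(ids))
  rk[ord] <- seq_along(ids)
  out <- data.frame(feature = ids, type = type,
                    pvalue = as.numeric(p), v0 = as.numeric(v0), v = v,
                    rank = rk, stringsAsFactors = FALSE)
  out <- out[order(out$rank), ]
  out$rank_in_type <- stats::ave(out$rank, out$type,
                                 FUN = function(r) rank(r, ties.method = "first"))
  rownames(out) <- NULL
  structure(out, class = c("association_scores", "data.frame"),
            features = features, iterations = iterations,
            residual = residual, variant = variant)
}

#' @export
print.association_scores <- function(x, n = 10L, ...) {
  v <- attr(x, "variant")
  cat(sprintf("<association_scores> %d features ranked%s\n", nrow(x),
              if (!is.null(v)) paste0(" (variant: ", v, ")") else ""))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat(sprintf("  ... %d more rows\n", nrow(x) - n))
  invisible(x)
}
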